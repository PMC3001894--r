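#' Configuration for survival-tree fitting
#'
#' Hyperparameters of the recursive-partitioning survival model. Defaults
#' are the classical values for this family of models: a node is
#' considered for splitting when it holds at least `minsplit` subjects,
#' each child must hold at least `minbucket`, a split must improve the
#' deviance by at least `cp` times the root deviance, and the pruning
#' level is chosen by `xval`-fold cross-validation.
#'
#' @param minsplit Minimum node size to attempt a split (default 20).
#' @param minbucket Minimum child size (default `ceiling(minsplit / 3)`).
#' @param cp Complexity threshold as a fraction of the root deviance
#'   (default 0.01).
#' @param xval Cross-validation folds for pruning (default 10).
#' @param seed Seed for the fold assignment (default NULL: folds drawn
#'   from the current RNG state).
#' @param rule Complexity-choice rule for [select_cp()]: `"1se"`
#'   (default) takes the smallest subtree within one standard error of
#'   the minimum cross-validated deviance, the conventional overfit guard
#'   for noisy small cohorts; `"min"` takes the minimising subtree.
#' @return A list of class `nr_tree_config`.
#' @export
tree_config <- function(minsplit = 20, minbucket = ceiling(minsplit / 3),
                        cp = 0.01, xval = 10, seed = NULL,
                        rule = c("1se", "min")) {
  rule <- match.arg(rule)
  stopifnot(minbucket >= 1, cp >= 0, cp < 1, xval >= 2)
  structure(list(minsplit = minsplit, minbucket = minbucket, cp = cp,
                 xval = xval, seed = seed, rule = rule),
            class = "nr_tree_config")
}

#' Exponential time rescaling
#'
#' Transforms follow-up times by the cohort Nelson-Aalen cumulative-hazard
#' estimate, so that under the transformed clock the cohort-level event
#' process has rate exactly 1 (sum of events over sum of rescaled times
#' equals 1). This is the rescaling under which an exponential survival
#' model can be fit by Poisson-deviance partitioning.
#'
#' @param time,event Survival vectors (times > 0, events 0/1); the cohort
#'   must contain at least one event.
#' @return Numeric vector of rescaled times, same order as the input.
#' @export
exp_rescale <- function(time, event) {
  check_surv(time, event)
  if (sum(event) == 0) {
    stop("no events in cohort: nothing to rescale", call. = FALSE)
  }
  ut <- sort(unique(time[event == 1]))
  increments <- vapply(ut, function(u) {
    sum(time == u & event == 1) / sum(time >= u)
  }, numeric(1))
  H <- cumsum(increments)
  idx <- findInterval(time, ut)
  ifelse(idx == 0, 0, H[pmax(idx, 1L)])
}

# Exponential-model deviance of a node from its sufficient statistics:
# D events, T total rescaled time, S = sum of log(rescaled time) over
# events. The d = 0 term uses the limit d*log(d/.) = 0.
dev_stat <- function(D, T, S) {
  if (D == 0) return(0)
  2 * (-D * log(D / T) - S)
}

#' Deviance reduction of a candidate partition
#'
#' Poisson/exponential deviance of the parent minus the summed deviance
#' of the two sides, each evaluated at its own maximum-likelihood rate
#' (events over rescaled time). Always nonnegative by likelihood nesting.
#'
#' @param d Event indicators (0/1).
#' @param t Rescaled times (see [exp_rescale()]).
#' @param left Logical vector: TRUE for subjects on the left side. Both
#'   sides must be nonempty.
#' @return The deviance reduction (a single nonnegative number).
#' @export
split_deviance <- function(d, t, left) {
  stopifnot(length(d) == length(t), length(left) == length(d))
  if (!any(left) || all(left)) stop("both sides must be nonempty")
  side_stats <- function(sel) {
    ev <- sel & d == 1
    c(D = sum(d[sel]), T = sum(t[sel]), S = sum(log(t[ev])))
  }
  p <- side_stats(rep(TRUE, length(d)))
  l <- side_stats(left)
  r <- side_stats(!left)
  unname(dev_stat(p["D"], p["T"], p["S"]) -
           dev_stat(l["D"], l["T"], l["S"]) -
           dev_stat(r["D"], r["T"], r["S"]))
}

# Best (gene, threshold) split of one node. Returns NULL when no
# admissible split exists. Deterministic tie-breaks: lowest gene index,
# then lowest threshold.
best_split <- function(expr, d, t, idx, minbucket, node_dev) {
  n <- length(idx)
  best <- NULL
  tol <- 1e-10
  logt_ev <- ifelse(d[idx] == 1, log(pmax(t[idx], 1e-300)), 0)
  for (gi in seq_len(nrow(expr))) {
    v <- expr[gi, idx]
    if (anyNA(v)) next
    ord <- order(v)
    vs <- v[ord]
    ds <- d[idx][ord]
    ts <- t[idx][ord]
    ss <- logt_ev[ord]
    cd <- cumsum(ds); ct <- cumsum(ts); cs <- cumsum(ss)
    Dtot <- cd[n]; Ttot <- ct[n]; Stot <- cs[n]
    ks <- which(vs[-n] < vs[-1])                 # distinct-value boundaries
    ks <- ks[ks >= minbucket & (n - ks) >= minbucket]
    if (!length(ks)) next
    for (k in ks) {
      red <- node_dev - dev_stat(cd[k], ct[k], cs[k]) -
        dev_stat(Dtot - cd[k], Ttot - ct[k], Stot - cs[k])
      if (red < -1e-8) {
        stop("internal error: negative deviance reduction")  # nocov
      }
      if (is.null(best) || red > best$reduction + tol) {
        best <- list(gene = gi,
                     threshold = unname((vs[k] + vs[k + 1]) / 2),
                     reduction = red)
      }
    }
  }
  best
}

#' Grow a survival tree
#'
#' Greedy recursive partitioning of subjects over expression covariates:
#' follow-up times are rescaled by [exp_rescale()], then at each node
#' every gene x midpoint-threshold split is enumerated and the one with
#' the largest Poisson-deviance reduction is taken, subject to the
#' `minsplit` / `minbucket` / `cp` rules of the configuration. Samples
#' with gene value strictly below the threshold go left. Ties are broken
#' deterministically (lowest gene index, then lowest threshold), so the
#' fitted tree is invariant to sample order.
#'
#' @param expr Genes x samples numeric matrix; column j is subject j.
#' @param time,event Survival vectors aligned with the columns of `expr`.
#' @param config A [tree_config()].
#' @return An object of class `nr_survtree`: a flat list of nodes (each
#'   with its size, events, rescaled exposure, event rate and, for
#'   internal nodes, the split gene and threshold), plus the training
#'   data needed by [select_cp()].
#' @export
grow <- function(expr, time, event, config = tree_config()) {
  stopifnot(is.matrix(expr), ncol(expr) == length(time))
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  }
  t_resc <- exp_rescale(time, event)
  tree <- grow_on_rescaled(expr, event, t_resc, seq_along(time), config)
  tree$expr <- expr
  tree$d <- event
  tree$t <- t_resc
  tree$config <- config
  tree$cp_table <- cp_sequence(tree)
  tree
}

# Growth on pre-rescaled times for a subject subset (used directly by the
# cross-validation in select_cp, which must not re-rescale).
grow_on_rescaled <- function(expr, d, t, subjects, config) {
  nodes <- list()
  root_dev <- NULL
  add_node <- function(idx, depth) {
    ev <- idx[d[idx] == 1]
    D <- length(ev); T <- sum(t[idx]); S <- sum(log(pmax(t[ev], 1e-300)))
    dev <- dev_stat(D, T, S)
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, n = length(idx), events = D,
                         exposure = T, rate = if (T > 0) D / T else 0,
                         deviance = dev, is_leaf = TRUE,
                         gene = NA_character_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         subjects = idx)
    if (is.null(root_dev)) root_dev <<- dev
    if (length(idx) >= config$minsplit && D > 0 && dev > 0) {
      sp <- best_split(expr, d, t, idx, config$minbucket, dev)
      if (!is.null(sp) && sp$reduction >= config$cp * root_dev) {
        v <- expr[sp$gene, idx]
        left_idx <- idx[v < sp$threshold]
        right_idx <- idx[v >= sp$threshold]
        nodes[[id]]$is_leaf <<- FALSE
        nodes[[id]]$gene <<- rownames(expr)[sp$gene]
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$reduction <<- sp$reduction
        nodes[[id]]$left <<- add_node(left_idx, depth + 1L)
        nodes[[id]]$right <<- add_node(right_idx, depth + 1L)
      }
    }
    id
  }
  add_node(subjects, 0L)
  structure(list(nodes = nodes, root = 1L, root_deviance = root_dev,
                 genes = rownames(expr)), class = "nr_survtree")
}

# Subtree summaries for cost-complexity pruning.
subtree_stats <- function(tree, id = tree$root) {
  nd <- tree$nodes[[id]]
  if (nd$is_leaf) {
    return(list(dev = nd$deviance, leaves = 1L))
  }
  l <- subtree_stats(tree, nd$left)
  r <- subtree_stats(tree, nd$right)
  list(dev = l$dev + r$dev, leaves = l$leaves + r$leaves)
}

# Collapse every internal node whose weakest-link complexity is <= alpha.
prune_at <- function(tree, alpha) {
  repeat {
    internal <- Filter(function(nd) !nd$is_leaf, tree$nodes)
    live <- Filter(function(nd) node_reachable(tree, nd$id), internal)
    if (!length(live)) break
    g <- vapply(live, function(nd) {
      st <- subtree_stats(tree, nd$id)
      (nd$deviance - st$dev) / (st$leaves - 1L)
    }, numeric(1))
    m <- min(g)
    if (m > alpha + 1e-12) break
    for (nd in live[g <= m + 1e-12]) {
      tree$nodes[[nd$id]]$is_leaf <- TRUE
    }
  }
  tree
}

node_reachable <- function(tree, id) {
  cur <- tree$root
  path <- c()
  reach <- function(i) {
    if (i == id) return(TRUE)
    nd <- tree$nodes[[i]]
    if (nd$is_leaf) return(FALSE)
    reach(nd$left) || reach(nd$right)
  }
  reach(cur)
}

# Weakest-link alpha sequence and the corresponding subtree sizes,
# expressed relative to the root deviance (a complexity table). Row k is
# the subtree reached by pruning at alpha = cp_k * root deviance; cp is
# nondecreasing from the full tree (row 1, cp = the grow threshold) to
# the root-only tree (last row).
cp_sequence <- function(tree) {
  alphas <- c()
  work <- tree
  rows <- list()
  repeat {
    st <- subtree_stats(work)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      nsplit = st$leaves - 1L, rel_deviance = st$dev / tree$root_deviance)
    internal <- Filter(function(nd) !nd$is_leaf && node_reachable(work, nd$id),
                       work$nodes)
    if (!length(internal)) break
    g <- vapply(internal, function(nd) {
      s <- subtree_stats(work, nd$id)
      (nd$deviance - s$dev) / (s$leaves - 1L)
    }, numeric(1))
    alphas <- c(alphas, min(g))
    work <- prune_at(work, min(g))
  }
  tbl <- dplyr::bind_rows(rows)
  tbl$cp <- cummax(c(tree$config$cp, alphas / tree$root_deviance))
  tbl[, c("cp", "nsplit", "rel_deviance")]
}

#' Prune a survival tree by cross-validated deviance
#'
#' Evaluates each candidate complexity level of the grown tree by
#' `xval`-fold cross-validation: trees are regrown on each training fold
#' (on the already-rescaled clock), pruned to the candidate level, and
#' scored by the held-out Poisson deviance at slightly shrunk leaf rates
#' (events + 1/2 over exposure + 1/2, which keeps held-out events in
#' empty-rate leaves finite). The subtree minimising the cross-validated
#' deviance is returned; ties go to the smaller tree.
#'
#' @param tree A tree from [grow()].
#' @param config Optional override of the configuration stored in the
#'   tree (e.g. a different `xval` or `seed`).
#' @param rule Complexity choice: `"1se"` (default) picks the smallest
#'   subtree whose cross-validated deviance is within one standard error
#'   of the minimum (the conventional overfit guard for noisy small
#'   cohorts); `"min"` picks the minimising subtree outright.
#' @return The pruned `nr_survtree`, with the chosen complexity in
#'   `$cp_chosen` and the cross-validation table in `$cv_table`.
#' @export
select_cp <- function(tree, config = NULL, rule = NULL) {
  config <- config %||% tree$config
  rule <- rule %||% config$rule %||% "1se"
  cp_tab <- tree$cp_table
  if (nrow(cp_tab) <= 1L) {
    tree$cp_chosen <- 1
    return(tree)
  }
  # candidate alphas, smallest tree first: geometric means of successive
  # breakpoints, so each candidate sits strictly inside the interval over
  # which one subtree of the main sequence is optimal
  cps <- rev(cp_tab$cp)
  cand <- sqrt(pmax(cps, 1e-12) * pmax(c(4 * cps[1], cps[-length(cps)]),
                                       1e-12))
  n <- length(tree$d)
  if (!is.null(config$seed)) {
    folds <- with_preserved_seed(config$seed, {
      sample(rep_len(seq_len(config$xval), n))
    })
  } else {
    folds <- sample(rep_len(seq_len(config$xval), n))
  }
  fold_dev <- matrix(0, config$xval, length(cand))
  for (f in seq_len(config$xval)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    if (sum(tree$d[train_idx]) == 0) next
    ft <- grow_on_rescaled(tree$expr, tree$d, tree$t, train_idx, tree$config)
    for (ci in seq_along(cand)) {
      pt <- prune_at(ft, cand[ci] * ft$root_deviance)
      fold_dev[f, ci] <- holdout_deviance(pt, tree$expr, tree$d, tree$t,
                                          test_idx)
    }
  }
  cv_dev <- colSums(fold_dev)
  imin <- which.min(cv_dev)             # ties -> smaller tree (listed first)
  best <- imin
  if (rule == "1se") {
    se <- stats::sd(fold_dev[, imin]) * sqrt(config$xval)
    best <- min(which(cv_dev <= cv_dev[imin] + se))
  }
  pruned <- prune_at(tree, cand[best] * tree$root_deviance)
  pruned$expr <- tree$expr
  pruned$d <- tree$d
  pruned$t <- tree$t
  pruned$config <- tree$config
  pruned$cp_table <- tree$cp_table
  pruned$cp_chosen <- cand[best]
  pruned$cv_table <- tibble::tibble(cp = cand, cv_deviance = cv_dev)
  pruned
}

holdout_deviance <- function(tree, expr, d, t, test_idx) {
  tot <- 0
  for (i in test_idx) {
    leaf <- route_sample(tree, stats::setNames(expr[, i], rownames(expr)))
    # unit-prior shrinkage toward the cohort rate (1 on the rescaled
    # clock): keeps held-out events in event-free leaves finite
    lam <- (leaf$events + 1) / (leaf$exposure + 1)
    di <- d[i]; ti <- t[i]
    term <- if (di == 1) di * log(di / (lam * max(ti, 1e-300))) else 0
    tot <- tot + 2 * (term - (di - lam * ti))
  }
  tot
}

route_sample <- function(tree, x) {
  id <- tree$root
  repeat {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) return(nd)
    v <- x[nd$gene]
    if (is.na(v)) stop("missing value for split gene ", nd$gene,
                       call. = FALSE)
    id <- if (v < nd$threshold) nd$left else nd$right
  }
}

#' Predict risk groups from a survival tree
#'
#' Routes each sample down the tree ("gene value < threshold goes left")
#' and labels it high-risk when its leaf's event rate exceeds the overall
#' rescaled cohort rate (1 by construction, taken from the root). A
#' root-only tree therefore labels everyone low-risk.
#'
#' @param tree A (typically pruned) `nr_survtree`.
#' @param expr Genes x samples matrix of new samples; all split genes
#'   must be present as rows.
#' @return A tibble with `sample` (column name or index), `rate` (leaf
#'   event rate) and `risk` ("high"/"low").
#' @export
predict_risk <- function(tree, expr) {
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1,
                                         dimnames = list(names(expr), "s1"))
  used <- tree_genes(tree)
  missing <- setdiff(used, rownames(expr))
  if (length(missing)) {
    stop("missing split gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref_rate <- tree$nodes[[tree$root]]$rate
  res <- lapply(seq_len(ncol(expr)), function(j) {
    leaf <- route_sample(tree, stats::setNames(expr[, j], rownames(expr)))
    tibble::tibble(sample = colnames(expr)[j] %||% as.character(j),
                   rate = leaf$rate,
                   risk = if (leaf$rate > ref_rate) "high" else "low")
  })
  dplyr::bind_rows(res)
}

#' Genes used by the (reachable, unpruned part of the) tree
#'
#' @param tree An `nr_survtree`.
#' @return Character vector of split-gene names, root first.
#' @export
tree_genes <- function(tree) {
  out <- character()
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) return(invisible())
    out <<- c(out, nd$gene)
    walk(nd$left)
    walk(nd$right)
  }
  walk(tree$root)
  unique(out)
}

#' @export
print.nr_survtree <- function(x, ...) {
  cat("Survival recursive-partitioning tree\n")
  walk <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$is_leaf) {
      cat(sprintf("%s* leaf: n=%d, events=%d, rate=%.3f\n",
                  pad, nd$n, nd$events, nd$rate))
    } else {
      cat(sprintf("%snode: n=%d, split %s < %.4g (left) / >= (right)\n",
                  pad, nd$n, nd$gene, nd$threshold))
      walk(nd$left, indent + 1L)
      walk(nd$right, indent + 1L)
    }
  }
  walk(x$root, 0L)
  invisible(x)
}

# Serializable skeleton (no training data) for results JSON.
tree_skeleton <- function(tree) {
  lapply(tree$nodes, function(nd) {
    keep <- nd[c("id", "n", "events", "exposure", "rate", "deviance",
                 "is_leaf", "gene", "threshold", "left", "right")]
    keep[!vapply(keep, function(v) length(v) == 1 && is.na(v), logical(1))]
  })
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards, so seeded subroutines do not perturb simulations.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
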