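#' Agglomerative average-linkage clustering of samples
#'
#' Hierarchical clustering of the sample columns of an expression matrix
#' with Euclidean distance and average linkage (UPGMA). Merges are
#' deterministic: when two pairs are equidistant, the pair whose
#' (lexicographically smallest, then second-smallest) member sample ids
#' sort first is merged, so the dendrogram is invariant to input order.
#'
#' @param expr Genes x samples matrix (log2 values); samples are
#'   clustered.
#' @param standardize Standardise each gene to mean 0 / SD 1 before
#'   computing distances (default FALSE: cluster the log2 values as
#'   given).
#' @return An object of class `nr_dendrogram` with `merge` and `height`
#'   in the usual agglomeration convention (negative entries are
#'   singleton samples, positive entries earlier merges) and `labels`
#'   (sample ids).
#' @export
hcluster <- function(expr, standardize = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  if (is.null(colnames(expr))) colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  if (standardize) {
    expr <- t(scale(t(expr)))
    expr[is.nan(expr)] <- 0      # constant genes carry no distance
  }
  bad_cols <- colSums(!is.finite(expr)) > 0
  if (any(bad_cols)) {
    stop("non-finite expression for sample(s): ",
         paste(colnames(expr)[bad_cols], collapse = ", "), call. = FALSE)
  }
  D <- as.matrix(stats::dist(t(expr)))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1L, ]
    stop("non-finite distance between samples ",
         colnames(expr)[bad[1]], " and ", colnames(expr)[bad[2]],
         call. = FALSE)
  }
  n <- ncol(expr)
  labels <- colnames(expr)
  # active clusters: id (hclust convention), size, representative label
  active <- data.frame(code = -seq_len(n), size = 1,
                       label = labels, stringsAsFactors = FALSE)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(active)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- D[i, j]
        pair_lab <- sort(c(active$label[i], active$label[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pair_lab[1] < best$lab[1] ||
              (pair_lab[1] == best$lab[1] && pair_lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d, lab = pair_lab)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(active$code[i], active$code[j]))
    height[step] <- best$d
    # average-linkage update (Lance-Williams with size weights)
    si <- active$size[i]; sj <- active$size[j]
    newd <- (si * D[i, ] + sj * D[j, ]) / (si + sj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(code = step, size = si + sj,
                               label = min(active$label[c(i, j)]),
                               stringsAsFactors = FALSE))
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "nr_dendrogram")
}

# Leaf labels under a node of the merge matrix (code < 0: singleton).
branch_members <- function(dendro, code) {
  if (code < 0) return(dendro$labels[-code])
  c(branch_members(dendro, dendro$merge[code, 1L]),
    branch_members(dendro, dendro$merge[code, 2L]))
}

#' Cut a dendrogram into two clusters with outlier stripping
#'
#' Descends from the root: while one branch of the current top split is
#' smaller than `min_cluster_size`, its members are marked outliers and
#' the walk recurses into the large branch. The first split whose
#' branches both hold at least `min_cluster_size` samples defines the
#' clusters; cluster 1 is the branch containing the lexicographically
#' smallest clustered sample id.
#'
#' @param dendro An `nr_dendrogram` from [hcluster()].
#' @param min_cluster_size Minimum samples per cluster (default 2).
#' @param max_outliers Maximum number of samples that may be stripped
#'   before giving up (default: a quarter of the samples).
#' @return A tibble with `sample_id` and `cluster`
#'   ("cluster1"/"cluster2"/"outlier").
#' @export
cut_two_clusters <- function(dendro, min_cluster_size = 2,
                             max_outliers = floor(length(dendro$labels) / 4)) {
  n <- length(dendro$labels)
  if (n < 2 * min_cluster_size) stop("too few samples", call. = FALSE)
  outliers <- character()
  code <- nrow(dendro$merge)  # root
  repeat {
    if (code < 0) stop("no qualifying two-cluster split", call. = FALSE)
    left <- branch_members(dendro, dendro$merge[code, 1L])
    right <- branch_members(dendro, dendro$merge[code, 2L])
    nl <- length(left); nr_ <- length(right)
    if (nl >= min_cluster_size && nr_ >= min_cluster_size) break
    small <- if (nl < min_cluster_size) left else right
    outliers <- c(outliers, small)
    if (length(outliers) > max_outliers) {
      stop("no qualifying two-cluster split within the outlier budget",
           call. = FALSE)
    }
    code <- if (nl < min_cluster_size) dendro$merge[code, 2L] else
      dendro$merge[code, 1L]
  }
  first <- min(c(left, right))
  c1 <- if (first %in% left) left else right
  c2 <- setdiff(c(left, right), c1)
  tibble::tibble(
    sample_id = dendro$labels,
    cluster = dplyr::case_when(
      dendro$labels %in% c1 ~ "cluster1",
      dendro$labels %in% c2 ~ "cluster2",
      TRUE ~ "outlier"))
}

#' Cluster demographics table
#'
#' Summarises clinical variables by cluster, in the style of a cohort
#' demographics table: numeric variables as mean +/- SE with a Welch t
#' test, categorical variables as counts per level with a two-sided
#' Fisher exact test on the 2 x K cluster-by-level table. Outlier samples
#' are excluded. Variables absent from the clinical table are skipped
#' with a message.
#'
#' @param assign Cluster assignment tibble from [cut_two_clusters()].
#' @param clinical Clinical table covering all non-outlier samples.
#' @param vars Variables to summarise; defaults to every clinical column
#'   except identifiers and follow-up times.
#' @return A tibble with `variable`, `cluster1`, `cluster2` (formatted
#'   summaries), `p.value` and `test`.
#' @export
cluster_table <- function(assign, clinical,
                          vars = setdiff(names(clinical),
                                         c("sample_id", "os_time",
                                           "rfs_time"))) {
  kept <- assign[assign$cluster != "outlier", ]
  miss <- setdiff(kept$sample_id, clinical$sample_id)
  if (length(miss)) {
    stop("clinical table missing sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cl <- clinical[match(kept$sample_id, clinical$sample_id), ]
  grp <- kept$cluster
  rows <- list()
  for (v in vars) {
    if (!v %in% names(cl)) {
      message("skipping absent clinical variable: ", v)
      next
    }
    x <- cl[[v]]
    categorical <- is.character(x) || is.factor(x) ||
      all(x %in% c(0, 1), na.rm = TRUE)
    if (!categorical) {
      x1 <- x[grp == "cluster1"]; x2 <- x[grp == "cluster2"]
      ht <- welch_t(x1, x2)
      rows[[v]] <- tibble::tibble(
        variable = v,
        cluster1 = sprintf("%.1f±%.1f", mean(x1),
                           stats::sd(x1) / sqrt(length(x1))),
        cluster2 = sprintf("%.1f±%.1f", mean(x2),
                           stats::sd(x2) / sqrt(length(x2))),
        p.value = ht$p.value, test = "welch_t")
    } else {
      tab <- table(grp, as.character(x))
      tab <- tab[c("cluster1", "cluster2"), , drop = FALSE]
      if (ncol(tab) < 2) {
        p <- 1
      } else {
        p <- fisher_exact_2xk(unclass(tab))
      }
      fmt <- function(r) paste(sprintf("%s:%d", colnames(tab), tab[r, ]),
                               collapse = " ")
      rows[[v]] <- tibble::tibble(variable = v, cluster1 = fmt(1),
                                  cluster2 = fmt(2), p.value = p,
                                  test = "fisher_exact")
    }
  }
  dplyr::bind_rows(rows)
}

#' Export a dendrogram in Newick format
#'
#' @param dendro An `nr_dendrogram`.
#' @param path Optional output path; when NULL the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(dendro, path = NULL) {
  render <- function(code) {
    if (code < 0) return(dendro$labels[-code])
    h <- dendro$height[code]
    sprintf("(%s,%s):%g", render(dendro$merge[code, 1L]),
            render(dendro$merge[code, 2L]), h)
  }
  nwk <- paste0(render(nrow(dendro$merge)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
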