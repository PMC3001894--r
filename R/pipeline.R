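#' @title Signature evaluation pipeline
#' @description Internal helpers plus the user-facing evaluation
#'   operations: leave-one-out cross-validation, cross-dataset
#'   validation, distillation into single-gene predictors, random
#'   gene-set permutation nulls, and clinical+expression combined models.
#' @name signature_pipeline
NULL

# Restrict a dataset's matrix to a signature, by gene symbol. Unmatched
# signature genes are dropped with a warning (symbol-level matching).
signature_matrix <- function(ds, signature) {
  if (is.null(signature)) return(ds$expression)
  signature <- unique(signature)
  found <- intersect(signature, rownames(ds$expression))
  if (!length(found)) {
    stop("no signature genes present in dataset; gene intersection empty",
         call. = FALSE)
  }
  if (length(found) < length(signature)) {
    warning("dropping ", length(signature) - length(found),
            " signature gene(s) absent from the dataset", call. = FALSE)
  }
  ds$expression[found, , drop = FALSE]
}

# Per-gene z-standardisation within a dataset; the harmonisation step
# applied before any cross-platform model transfer.
standardize_genes <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  sdv[sdv == 0] <- 1
  (mat - mu) / sdv
}

fit_tree_model <- function(expr, time, event, config) {
  select_cp(grow(expr, time, event, config))
}

# Assemble KM / log-rank / Cox summaries from predicted labels.
validation_result <- function(labels, time, event, harmonization = "none") {
  stopifnot(nrow(labels) == length(time))
  out <- list(labels = labels, n_high = sum(labels$risk == "high"),
              n_low = sum(labels$risk == "low"), degenerate = FALSE,
              logrank_p = NA_real_, hr = NA_real_,
              hr_ci = c(NA_real_, NA_real_), cox_p = NA_real_,
              km = NULL, harmonization = harmonization)
  d <- data.frame(time = time, event = event, risk = labels$risk)
  if (out$n_high == 0 || out$n_low == 0) {
    out$degenerate <- TRUE
    class(out) <- "nr_validation"
    return(out)
  }
  out$km <- km_fit(d, group = "risk")
  lr <- logrank_test(d, group = "risk")
  out$logrank_p <- lr$p.value
  out$logrank_statistic <- lr$statistic
  d$risk_high <- as.numeric(d$risk == "high")
  cox <- withCallingHandlers(
    tryCatch(cox_fit(d, "risk_high"), error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(cox)) {
    co <- cox$coefficients
    out$hr <- co$hr
    out$hr_ci <- c(co$conf.low, co$conf.high)
    out$cox_p <- co$p.value
    out$cox_flagged <- cox$infinite_beta
  }
  class(out) <- "nr_validation"
  out
}

#' Leave-one-out cross-validation of a signature risk model
#'
#' For each sample, a pruned survival tree is fit on the remaining n - 1
#' samples (restricted to the signature genes) and the held-out sample is
#' labelled by [predict_risk()]. The assembled out-of-fold labels are
#' summarised by Kaplan-Meier curves, a log-rank test and a Cox hazard
#' ratio of predicted high- vs low-risk. A training fold without events
#' cannot be rescaled; its held-out sample is labelled low-risk (the
#' cohort-rate rule) and flagged.
#'
#' @param ds An [nr_dataset()] with at least 10 samples.
#' @param signature Character vector of gene symbols, or NULL for all
#'   genes.
#' @param config A [tree_config()].
#' @return An object of class `nr_validation` (labels, KM curves,
#'   log-rank p, Cox HR with 95% CI, degenerate flag).
#' @export
loocv_evaluate <- function(ds, signature = NULL, config = tree_config()) {
  expr <- signature_matrix(ds, signature)
  n <- ncol(expr)
  if (n < 10) stop("leave-one-out needs at least 10 samples", call. = FALSE)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    lab <- tryCatch({
      fit <- fit_tree_model(expr[, tr, drop = FALSE],
                            ds$time[tr], ds$event[tr], config)
      predict_risk(fit, expr[, i])$risk
    }, error = function(e) NA_character_)
    flagged <- is.na(lab)
    labels[[i]] <- tibble::tibble(sample = colnames(expr)[i],
                                  risk = ifelse(flagged, "low", lab),
                                  fold_flagged = flagged)
  }
  validation_result(dplyr::bind_rows(labels), ds$time, ds$event)
}

#' Train a signature model on one cohort and validate on another
#'
#' Genes are matched across the datasets by symbol; both matrices are
#' per-gene z-standardised within their own dataset (so thresholds
#' learned on one platform transfer in standardised units), a pruned
#' survival tree is fit on the training cohort, and every test sample is
#' labelled and summarised as in [loocv_evaluate()].
#'
#' @param train,test [nr_dataset()] objects.
#' @param signature Gene symbols, or NULL for all shared genes.
#' @param config A [tree_config()].
#' @param harmonize Apply the per-gene standardisation (default TRUE).
#'   With FALSE the raw log2 values are used on both sides (appropriate
#'   when train and test share a platform and scale).
#' @return An `nr_validation` for the test cohort, with the fitted tree
#'   attached as `$model`.
#' @export
train_test_validate <- function(train, test, signature = NULL,
                                config = tree_config(), harmonize = TRUE) {
  sig <- signature %||% rownames(train$expression)
  shared <- intersect(intersect(sig, rownames(train$expression)),
                      rownames(test$expression))
  if (!length(shared)) {
    stop("no shared genes between train and test after matching; ",
         "intersection is empty", call. = FALSE)
  }
  shared <- sort(shared)   # gene-order invariance
  tr_mat <- train$expression[shared, , drop = FALSE]
  te_mat <- test$expression[shared, , drop = FALSE]
  if (harmonize) {
    tr_mat <- standardize_genes(tr_mat)
    te_mat <- standardize_genes(te_mat)
  }
  fit <- fit_tree_model(tr_mat, train$time, train$event, config)
  labels <- predict_risk(fit, te_mat)
  res <- validation_result(labels, test$time, test$event,
                           harmonization = if (harmonize)
                             "per-gene z within dataset" else "none")
  res$model <- fit
  res
}

#' Distill a signature into ordered single-gene predictors
#'
#' Fits the pruned model on the signature (minus exclusions) and reports
#' the genes actually used; the root split gene is recorded and excluded,
#' and the fit repeated, yielding an ordered list of single-gene
#' predictors. Iteration stops when the model prunes to a leaf (an empty
#' predictor list is a reported outcome, not an error).
#'
#' @param ds An [nr_dataset()].
#' @param signature Gene symbols, or NULL for all genes.
#' @param exclude Genes to exclude before the first fit.
#' @param max_iter Maximum number of distillation rounds (default 2,
#'   mirroring primary/secondary predictor discovery).
#' @param config A [tree_config()].
#' @return A tibble with `iteration`, `root_gene` and `genes_used`
#'   (list-column); zero rows when the first model is a leaf.
#' @export
distill <- function(ds, signature = NULL, exclude = character(),
                    max_iter = 2, config = tree_config()) {
  sig <- signature %||% rownames(ds$expression)
  sig <- setdiff(sig, exclude)
  if (!length(sig)) stop("signature empty after exclusions", call. = FALSE)
  rows <- list()
  for (it in seq_len(max_iter)) {
    if (!length(sig)) break
    expr <- signature_matrix(ds, sig)
    fit <- fit_tree_model(expr, ds$time, ds$event, config)
    used <- tree_genes(fit)
    if (!length(used)) break
    rows[[it]] <- tibble::tibble(iteration = it, root_gene = used[1],
                                 genes_used = list(used))
    sig <- setdiff(sig, used[1])
  }
  if (!length(rows)) {
    return(tibble::tibble(iteration = integer(), root_gene = character(),
                          genes_used = list()))
  }
  dplyr::bind_rows(rows)
}

#' Random-gene-set permutation null
#'
#' Draws `n_sets` random gene sets of size `set_size` from a genome-wide
#' dataset, and for each runs the full train/test validation on a seeded
#' half split of the samples, recording the test log-rank p-value. The
#' empirical p is the fraction of random sets reaching `reference_p`.
#' Degenerate fits (all test samples in one risk group) are recorded as
#' NA and excluded from the denominator with a warning.
#'
#' @param ds An [nr_dataset()] whose gene pool exceeds `set_size`.
#' @param set_size Genes per random set (default 48).
#' @param n_sets Number of random sets (default 1000).
#' @param reference_p Significance level attained by the signature under
#'   test; the empirical p counts random sets doing at least as well.
#' @param seed Integer seed for the sample split and the gene draws.
#' @param config A [tree_config()].
#' @param plus_one Use the (k+1)/(n+1) permutation-p variant instead of
#'   the plain fraction k/n (default FALSE).
#' @return An object of class `nr_permnull`: `pvalues` (length
#'   `n_sets`, NA for degenerate fits), `empirical_p`, `n_valid`,
#'   `reference_p`, `seed`.
#' @export
random_geneset_null <- function(ds, set_size = 48, n_sets = 1000,
                                reference_p = 0.05, seed = 1L,
                                config = tree_config(), plus_one = FALSE) {
  pool <- rownames(ds$expression)
  if (length(pool) <= set_size) {
    stop("gene pool must exceed the set size", call. = FALSE)
  }
  n <- ncol(ds$expression)
  set.seed(seed)
  split <- sample(rep_len(c(TRUE, FALSE), n))
  mk <- function(sel) {
    nr_dataset(ds$expression[, sel, drop = FALSE],
               ds$clinical[sel, ], platform = ds$platform,
               endpoint = ds$endpoint)
  }
  train <- mk(split)
  test <- mk(!split)
  pvals <- rep(NA_real_, n_sets)
  for (k in seq_len(n_sets)) {
    genes <- sample(pool, set_size)
    res <- tryCatch(
      suppressWarnings(train_test_validate(train, test, genes, config)),
      error = function(e) NULL)
    if (!is.null(res) && !res$degenerate) pvals[k] <- res$logrank_p
  }
  n_valid <- sum(!is.na(pvals))
  if (n_valid < n_sets) {
    warning(n_sets - n_valid, " degenerate fit(s) excluded from the ",
            "permutation denominator", call. = FALSE)
  }
  k_hit <- sum(pvals <= reference_p, na.rm = TRUE)
  emp <- if (plus_one) (k_hit + 1) / (n_valid + 1) else
    if (n_valid > 0) k_hit / n_valid else NA_real_
  structure(list(pvalues = pvals, empirical_p = emp, n_sets = n_sets,
                 n_valid = n_valid, reference_p = reference_p,
                 seed = seed, plus_one = plus_one),
            class = "nr_permnull")
}

#' Compare a signature's p-value distribution against a random-gene null
#'
#' Two-sample Kolmogorov-Smirnov comparison of two collections of
#' p-values (e.g. univariate Cox p-values of the signature genes versus
#' random genes), together with the empirical CDF table of both samples.
#'
#' @param signature_pvals,random_pvals Nonempty numeric vectors of
#'   p-values.
#' @return A list with `ks` (tibble: statistic, p.value) and `cdf`
#'   (tibble: source, p, cdf).
#' @export
pvalue_cdf_compare <- function(signature_pvals, random_pvals) {
  ks <- ks_two_sample(signature_pvals, random_pvals)
  cdf_tbl <- function(p, source) {
    p <- sort(p)
    tibble::tibble(source = source, p = p,
                   cdf = seq_along(p) / length(p))
  }
  list(ks = ks,
       cdf = dplyr::bind_rows(cdf_tbl(signature_pvals, "signature"),
                              cdf_tbl(random_pvals, "random")))
}

#' Combined clinical + expression risk model
#'
#' Summarises the signature submatrix by its first two principal
#' components (genes centred and scaled on the training cohort, test
#' samples projected with the training rotation), appends numerically
#' coded clinical covariates (ordinal stage, 0/1 flags), fits a pruned
#' survival tree on this combined design, and validates on the test
#' cohort. With degenerate expression the principal components are
#' constant and the model reduces to a clinical-only tree.
#'
#' @param train,test [nr_dataset()] objects.
#' @param signature Gene symbols (>= 2 required).
#' @param clinical_vars Clinical columns to include; `stage` is recoded
#'   to 1-4 and `gender` to 0/1 automatically.
#' @param config A [tree_config()].
#' @return An `nr_validation` with the fitted tree attached as `$model`
#'   and the training PC rotation as `$rotation`.
#' @export
combined_clinical_model <- function(train, test, signature = NULL,
                                    clinical_vars = c("gender", "age",
                                                      "stage",
                                                      "adjuvant_chemo",
                                                      "adjuvant_rt"),
                                    config = tree_config()) {
  sig <- signature %||% rownames(train$expression)
  shared <- sort(intersect(intersect(sig, rownames(train$expression)),
                           rownames(test$expression)))
  if (length(shared) < 2) {
    stop("need at least two signature genes for principal components",
         call. = FALSE)
  }
  tr <- t(train$expression[shared, , drop = FALSE])
  te <- t(test$expression[shared, , drop = FALSE])
  mu <- colMeans(tr)
  sdv <- apply(tr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  trs <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
  tes <- sweep(sweep(te, 2, mu), 2, sdv, "/")
  pc <- stats::prcomp(trs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(min(2, ncol(pc$rotation))), drop = FALSE]
  feat <- function(scores, ds) {
    cli <- encode_clinical(ds$clinical, clinical_vars)
    t(cbind(PC1 = scores[, 1],
            PC2 = if (ncol(scores) > 1) scores[, 2] else 0,
            cli))
  }
  tr_feat <- feat(trs %*% rot, train)
  te_feat <- feat(tes %*% rot, test)
  fit <- fit_tree_model(tr_feat, train$time, train$event, config)
  labels <- predict_risk(fit, te_feat)
  res <- validation_result(labels, test$time, test$event,
                           harmonization = "train-cohort PC projection")
  res$model <- fit
  res$rotation <- rot
  res
}

encode_clinical <- function(clinical, vars) {
  out <- lapply(vars, function(v) {
    if (!v %in% names(clinical)) {
      stop("clinical variable absent: ", v, call. = FALSE)
    }
    x <- clinical[[v]]
    if (v == "stage") return(match(x, c("I", "II", "III", "IV")))
    if (is.character(x) || is.factor(x)) {
      return(as.numeric(factor(x)) - 1)
    }
    as.numeric(x)
  })
  mat <- do.call(cbind, out)
  colnames(mat) <- vars
  mat
}

#' Validate on a clinical subset of the test cohort
#'
#' Trains on the full training cohort and evaluates only the test samples
#' satisfying a clinical predicate (e.g. `stage == "I"`).
#'
#' @param train,test [nr_dataset()] objects.
#' @param signature Gene symbols or NULL.
#' @param subset A predicate on the test clinical table, unquoted (e.g.
#'   `stage == "I"`), or a logical vector.
#' @param config,harmonize As in [train_test_validate()].
#' @return An `nr_validation` for the filtered test samples.
#' @export
subset_evaluate <- function(train, test, signature = NULL, subset,
                            config = tree_config(), harmonize = TRUE) {
  keep <- rlang::eval_tidy(rlang::enquo(subset), data = test$clinical)
  if (!any(keep)) stop("empty test subset", call. = FALSE)
  sub <- nr_dataset(test$expression[, keep, drop = FALSE],
                    test$clinical[keep, ], platform = test$platform,
                    endpoint = test$endpoint)
  train_test_validate(train, sub, signature, config, harmonize)
}

#' Prognostic evaluation of paired normal tissue
#'
#' Runs the leave-one-out evaluation and single-gene distillation on the
#' adjacent-normal expression matrix of a cohort against the chosen
#' endpoint (overall survival or recurrence-free survival).
#'
#' @param cohort An `nr_cohort` with a normal-tissue matrix, or an
#'   [nr_dataset()] whose `normal_expression` is set.
#' @param endpoint "os" or "rfs".
#' @param signature Gene symbols or NULL.
#' @param config A [tree_config()].
#' @return A list with `validation` (`nr_validation` from LOOCV) and
#'   `distilled` (tibble from [distill()]).
#' @export
normal_tissue_evaluate <- function(cohort, endpoint = c("rfs", "os"),
                                   signature = NULL,
                                   config = tree_config()) {
  endpoint <- match.arg(endpoint)
  if (inherits(cohort, "nr_cohort")) {
    ds <- as_dataset(cohort, endpoint = endpoint, tissue = "normal")
  } else {
    if (is.null(cohort$normal_expression)) {
      stop("no normal-tissue matrix present", call. = FALSE)
    }
    ds <- nr_dataset(cohort$normal_expression, cohort$clinical,
                     platform = cohort$platform, endpoint = endpoint)
  }
  list(validation = loocv_evaluate(ds, signature, config),
       distilled = distill(ds, signature, config = config))
}
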