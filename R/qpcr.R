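#' Amplification efficiency from a standard-curve slope
#'
#' Converts the slope of a standard curve (threshold cycle regressed on
#' log10 template quantity) into a per-cycle amplification efficiency
#' \eqn{e = 10^{-1/slope}}. A perfectly doubling reaction has slope
#' -3.3219 and efficiency 2.
#'
#' @param slope Standard-curve slope in cycles per log10(quantity); must be
#'   negative (more template, earlier crossing).
#' @return Efficiency as fold amplification per cycle. A warning is issued
#'   for efficiencies outside (1, 2.2], which usually indicate a bad curve.
#' @export
#' @examples
#' pcr_efficiency(-3.3219)  # ~2, perfect doubling
pcr_efficiency <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope >= 0) {
    stop("invalid standard curve: slope must be a single negative number",
         call. = FALSE)
  }
  e <- 10^(-1 / slope)
  if (e <= 1 || e > 2.2) {
    warning(sprintf("efficiency %.4f outside the usual (1, 2.2] range", e),
            call. = FALSE)
  }
  e
}

#' Relative template quantity of a single well
#'
#' @param e Amplification efficiency (> 1), see [pcr_efficiency()].
#' @param ct Threshold cycle (cycle time) of the well, >= 0.
#' @return Relative quantity \eqn{e^{-Ct}}; monotone decreasing in `ct`.
#' @export
well_quantity <- function(e, ct) {
  stopifnot(is.numeric(e), all(e > 1), is.numeric(ct), all(ct >= 0))
  e^(-ct)
}

#' Fit a standard curve by least squares
#'
#' Ordinary least-squares regression of threshold cycle on log10 template
#' quantity over a dilution series, the same fit instrument software
#' performs. Zero-template (no-template-control) points are dropped.
#'
#' @param quantity Template quantities of the dilution series (same units
#'   throughout, e.g. ng).
#' @param ct Observed threshold cycles, same length as `quantity`.
#' @return A tibble with one row: `slope`, `intercept`, `efficiency`,
#'   `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(length(quantity) == length(ct))
  keep <- is.finite(quantity) & quantity > 0 & is.finite(ct)
  if (sum(keep) < 2L) {
    stop("need at least two finite positive-quantity points", call. = FALSE)
  }
  x <- log10(quantity[keep])
  y <- ct[keep]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  tibble::tibble(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    efficiency = pcr_efficiency(slope),
    r_squared = summary(fit)$r.squared,
    n_points = sum(keep)
  )
}

cv_of <- function(x) {
  if (mean(x) <= 0) return(NA_real_)
  stats::sd(x) / mean(x)
}

#' Triplicate outlier filter on the quantity scale
#'
#' Summarises replicate well quantities and applies the coefficient-of-
#' variation quality gate: when the CV (sd/mean) of the replicates exceeds
#' `cv_max`, the single point whose removal most reduces the CV is dropped.
#' At most one point is ever removed; if the remaining pair still exceeds
#' the gate the pair is kept and flagged. Ties in the CV reduction are
#' broken by dropping the latest-indexed well, so the result is
#' deterministic.
#'
#' @param quantities Numeric vector of 2 or 3 replicate quantities
#'   (already on the quantity scale, i.e. after the efficiency^-Ct
#'   transform).
#' @param cv_max CV gate, default 0.17 (see
#'   [max_cv_for_fold_detection()] for where that number comes from).
#' @return A list with `values` (kept quantities), `avg`, `stdev`, `cv`,
#'   `outlier_removed` (logical), `removed_index` (index into the input or
#'   NA) and `qc_warning` (TRUE when the gate is still exceeded after the
#'   one allowed removal, or when only a pair was supplied and it fails
#'   the gate).
#' @export
filter_outlier <- function(quantities, cv_max = 0.17) {
  quantities <- as.numeric(quantities)
  n <- length(quantities)
  if (n < 2L || n > 3L || anyNA(quantities)) {
    stop("need 2 or 3 finite replicate quantities", call. = FALSE)
  }
  res <- list(values = quantities, avg = mean(quantities),
              stdev = stats::sd(quantities), cv = cv_of(quantities),
              outlier_removed = FALSE, removed_index = NA_integer_,
              qc_warning = FALSE)
  if (is.na(res$cv) || res$cv <= cv_max) return(res)
  if (n == 2L) {           # a pair cannot lose a point and remain a replicate
    res$qc_warning <- TRUE
    return(res)
  }
  drop_cv <- vapply(seq_len(n), function(i) cv_of(quantities[-i]), numeric(1))
  # latest index wins ties: scan from the end for the minimising removal
  best <- n + 1L - which.min(rev(drop_cv))
  kept <- quantities[-best]
  res$values <- kept
  res$avg <- mean(kept)
  res$stdev <- stats::sd(kept)
  res$cv <- cv_of(kept)
  res$outlier_removed <- TRUE
  res$removed_index <- best
  res$qc_warning <- isTRUE(res$cv > cv_max)
  res
}

#' Below-detection call for a replicate set
#'
#' A gene/sample replicate is scored below detection when the mean
#' threshold cycle exceeds `ct_max` (strict inequality), i.e. too little
#' template to quantify.
#'
#' @param ct_values Threshold cycles of the replicate wells.
#' @param ct_max Detection limit in cycles, default 34.
#' @return TRUE when mean(ct) > ct_max.
#' @export
below_detection <- function(ct_values, ct_max = 34) {
  mean(ct_values) > ct_max
}

#' Reference-gene normalisation with error propagation
#'
#' Normalised expression is the ratio of the target replicate mean to the
#' reference (e.g. 18S rRNA) replicate mean; its standard deviation is
#' propagated as value * sqrt(cv_ref^2 + cv_target^2).
#'
#' @param nr Replicate summary for the gene of interest, as returned by
#'   [filter_outlier()] (needs `avg` and `cv`).
#' @param ref Replicate summary for the reference gene.
#' @return A list with `value`, `stdev` and `log2_value`.
#' @export
normalize_expression <- function(nr, ref) {
  if (!is.finite(ref$avg) || ref$avg <= 0) {
    stop("reference quantity mean must be positive", call. = FALSE)
  }
  value <- nr$avg / ref$avg
  cv_nr <- if (is.na(nr$cv)) 0 else nr$cv
  cv_ref <- if (is.na(ref$cv)) 0 else ref$cv
  list(value = value,
       stdev = value * sqrt(cv_ref^2 + cv_nr^2),
       log2_value = log2(value))
}

#' Largest replicate CV that still resolves a fold change
#'
#' Finds the largest common coefficient of variation c such that a
#' two-sided two-sample t test (n replicates per group, pooled variance,
#' one group at mean mu and the other at fold*mu, each group's SD equal to
#' c times its own mean) attains significance at level 1 - confidence.
#' Setting the t statistic equal to the critical value and solving gives
#' \deqn{c = (fold - 1) / (t_{crit} \sqrt{(fold^2 + 1)/n}).}
#' With the defaults (2-fold, 99% confidence, triplicates) this evaluates
#' to 0.168, i.e. the 17% gate applied to replicate quantities.
#'
#' @param fold Fold change to resolve, > 1 (default 2).
#' @param confidence Confidence level in (0, 1), default 0.99.
#' @param n_replicates Replicates per group, >= 2 (default 3).
#' @return The CV bound as a fraction.
#' @export
max_cv_for_fold_detection <- function(fold = 2, confidence = 0.99,
                                      n_replicates = 3) {
  if (!is.numeric(fold) || fold <= 1) {
    stop("fold must exceed 1: no detectable change otherwise", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0,1)")
  if (n_replicates < 2) stop("need at least two replicates per group")
  alpha <- 1 - confidence
  df <- 2 * n_replicates - 2
  t_crit <- stats::qt(1 - alpha / 2, df)
  cv <- (fold - 1) / (t_crit * sqrt((fold^2 + 1) / n_replicates))
  if (!is.finite(cv) || cv <= 0) stop("no admissible CV bound", call. = FALSE)
  cv
}

#' Assemble a log2 expression matrix from plate wells
#'
#' Runs the full relative-quantification chain for a long table of wells:
#' per gene x sample replicate, quantities are computed from the gene's
#' standard-curve efficiency, the CV outlier gate is applied, values are
#' normalised to the reference gene of the same sample, and the log2
#' normalised values are assembled into a genes x samples matrix.
#' Replicates whose mean Ct exceeds `ct_max` are masked as below
#' detection; masked cells are imputed, before the log2 transform, at half
#' the smallest detected normalised value of that gene (a conventional
#' detection floor) and flagged in the QC report. A fully masked matrix is
#' returned with `all_masked = TRUE` so downstream fits can refuse it.
#'
#' @param wells Data frame with columns `sample_id`, `gene_id`, `well`
#'   (replicate index, unused beyond ordering) and `ct`.
#' @param curves Data frame with columns `gene_id` and either `efficiency`
#'   or `slope` (converted via [pcr_efficiency()]). Must cover every gene
#'   in `wells` including the reference.
#' @param reference_gene Gene id of the endogenous reference (e.g. 18S).
#' @param cv_max,ct_max QC gates, see [filter_outlier()] and
#'   [below_detection()].
#' @return A list of class `nr_plate`: `expression` (genes x samples log2
#'   matrix, reference row excluded), `mask` (logical matrix, TRUE =
#'   below detection), `qc` (tibble of per-replicate QC flags),
#'   `all_masked`.
#' @export
process_plate <- function(wells, curves, reference_gene,
                          cv_max = 0.17, ct_max = 34) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(wells)))
  if (!"efficiency" %in% names(curves)) {
    curves$efficiency <- vapply(curves$slope, pcr_efficiency, numeric(1))
  }
  missing_curves <- setdiff(unique(wells$gene_id), curves$gene_id)
  if (length(missing_curves)) {
    stop("no standard curve for gene(s): ",
         paste(missing_curves, collapse = ", "), call. = FALSE)
  }
  eff <- stats::setNames(curves$efficiency, curves$gene_id)

  samples <- sort(unique(wells$sample_id))
  genes <- sort(setdiff(unique(wells$gene_id), reference_gene))
  has_ref <- vapply(samples, function(s) {
    any(wells$sample_id == s & wells$gene_id == reference_gene)
  }, logical(1))
  if (!all(has_ref)) {
    stop("missing reference gene wells for sample(s): ",
         paste(samples[!has_ref], collapse = ", "), call. = FALSE)
  }

  summarise_rep <- function(sample, gene) {
    ct <- wells$ct[wells$sample_id == sample & wells$gene_id == gene]
    ct <- sort(ct)  # well input order must not matter
    masked <- below_detection(ct, ct_max)
    meas <- filter_outlier(well_quantity(eff[[gene]], ct), cv_max)
    meas$below_detection <- masked
    meas
  }

  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  mask <- matrix(FALSE, length(genes), length(samples),
                 dimnames = list(genes, samples))
  qc <- list()
  for (s in samples) {
    ref <- summarise_rep(s, reference_gene)
    if (ref$below_detection) {
      stop("reference gene below detection in sample ", s, call. = FALSE)
    }
    for (g in genes) {
      meas <- summarise_rep(s, g)
      qc[[length(qc) + 1L]] <- tibble::tibble(
        sample_id = s, gene_id = g,
        cv = meas$cv, outlier_removed = meas$outlier_removed,
        cv_warning = meas$qc_warning, below_detection = meas$below_detection)
      if (meas$below_detection) {
        mask[g, s] <- TRUE
      } else {
        mat[g, s] <- normalize_expression(meas, ref)$value
      }
    }
  }

  # detection floor: half the smallest detected normalised value per gene
  for (g in genes) {
    if (any(mask[g, ]) && any(!mask[g, ])) {
      mat[g, mask[g, ]] <- min(mat[g, !mask[g, ]], na.rm = TRUE) / 2
    }
  }
  all_masked <- all(mask)
  log2mat <- log2(mat)
  structure(list(expression = log2mat, mask = mask,
                 qc = dplyr::bind_rows(qc), all_masked = all_masked),
            class = "nr_plate")
}
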