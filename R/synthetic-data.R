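#' Specification of a synthetic lung-cancer cohort
#'
#' Describes a cohort with the statistical structure the downstream
#' analyses assume: log2 expression for `n_genes` genes in `n_patients`
#' tumors (optionally with paired adjacent-normal tissue), survival
#' driven by planted single-gene threshold effects, and uniform
#' administrative censoring. Defaults emulate a small deeply phenotyped
#' qPCR cohort: 30 patients, a 48-gene panel, one planted gene whose low
#' expression carries a five-fold hazard (high risk below the threshold,
#' as in a protective-gene signature).
#'
#' @param n_patients Number of patients (>= 4).
#' @param n_genes Number of genes in the panel.
#' @param planted_genes Data frame with one row per planted gene and
#'   columns `gene` (row index), `threshold` (log2 units), `rate_below`,
#'   `rate_above` (hazard in events per month for samples below/above the
#'   threshold) and optionally `endpoint` ("os" or "rfs", default "os")
#'   and `component` (integer label; genes sharing a label share the
#'   bimodal side draw, emulating co-expressed genes that carry the same
#'   prognostic signal — by default every gene has its own component).
#'   May be NULL or zero rows for a fully null cohort.
#' @param baseline_hazard Hazard (events/month) shared by all samples for
#'   endpoints without planted genes; planted genes act multiplicatively
#'   relative to it.
#' @param censor_horizon Upper bound (months) of the uniform
#'   administrative-censoring time. Ignored when
#'   `admin_censor_frac_target` is given.
#' @param admin_censor_frac_target Optional target fraction of censored
#'   subjects in (0, 1); when given, the censor horizon is calibrated
#'   analytically against the planted hazard mixture.
#' @param paired_normal_corr Target Pearson correlation between the tumor
#'   and paired-normal matrices (pooled over all entries), or NULL for no
#'   normal matrix.
#' @param platform "qpcr" (full dynamic range) or "microarray"
#'   (compressed dynamic range with extra measurement noise).
#' @param noise_sd Within-gene expression SD in log2 units.
#' @param planted_tissue Which tissue carries the planted expression
#'   structure, "tumor" (default) or "normal".
#' @param seed Integer seed; identical specs with identical seeds give
#'   bit-identical cohorts.
#' @return A list of class `nr_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 30, n_genes = 48,
                        planted_genes = default_planted(),
                        baseline_hazard = 0.02, censor_horizon = 60,
                        admin_censor_frac_target = NULL,
                        paired_normal_corr = 0.87,
                        platform = c("qpcr", "microarray"),
                        noise_sd = 1, planted_tissue = c("tumor", "normal"),
                        seed = 1L) {
  platform <- match.arg(platform)
  planted_tissue <- match.arg(planted_tissue)
  if (n_patients < 4) stop("need at least 4 patients", call. = FALSE)
  if (baseline_hazard <= 0 || censor_horizon <= 0) {
    stop("rates and horizon must be positive", call. = FALSE)
  }
  if (!is.null(planted_genes) && nrow(planted_genes) > 0) {
    if (!"endpoint" %in% names(planted_genes)) planted_genes$endpoint <- "os"
    if (!"component" %in% names(planted_genes)) {
      planted_genes$component <- seq_len(nrow(planted_genes))
    }
    stopifnot(all(planted_genes$gene >= 1),
              all(planted_genes$gene <= n_genes),
              all(is.finite(planted_genes$threshold)),
              all(planted_genes$rate_below > 0),
              all(planted_genes$rate_above > 0),
              all(planted_genes$endpoint %in% c("os", "rfs")))
  }
  if (!is.null(paired_normal_corr) &&
      (paired_normal_corr < 0 || paired_normal_corr > 1)) {
    stop("paired_normal_corr must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(admin_censor_frac_target) &&
      (admin_censor_frac_target <= 0 || admin_censor_frac_target >= 1)) {
    stop("admin_censor_frac_target must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 planted_genes = planted_genes,
                 baseline_hazard = baseline_hazard,
                 censor_horizon = censor_horizon,
                 admin_censor_frac_target = admin_censor_frac_target,
                 paired_normal_corr = paired_normal_corr,
                 platform = platform, noise_sd = noise_sd,
                 planted_tissue = planted_tissue,
                 seed = as.integer(seed)),
            class = "nr_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_planted <- function() {
  tibble::tibble(gene = 1L, threshold = -8.5,
                 rate_below = 0.1, rate_above = 0.02, endpoint = "os")
}

# Calibrate the uniform-censoring horizon so the expected censored
# fraction matches the target. For T ~ Exp(lambda) and C ~ U(0, h),
# P(censored) = (1 - exp(-lambda h)) / (lambda h); mix over risk classes.
calibrate_horizon <- function(rates, weights, target) {
  frac <- function(h) {
    sum(weights * (1 - exp(-rates * h)) / (rates * h)) - target
  }
  stats::uniroot(frac, c(1e-6, 1e6), tol = 1e-10)$root
}

# Per-class hazard for one endpoint: baseline times the product of
# planted rate ratios on the sample's side of each threshold.
planted_hazard <- function(spec, endpoint, sides) {
  pg <- spec$planted_genes
  lam <- rep(spec$baseline_hazard, spec$n_patients)
  if (is.null(pg)) return(lam)
  pg <- pg[pg$endpoint == endpoint, , drop = FALSE]
  if (!nrow(pg)) return(lam)
  for (k in seq_len(nrow(pg))) {
    below <- sides[, as.character(pg$gene[k])]
    rate <- ifelse(below, pg$rate_below[k], pg$rate_above[k])
    lam <- lam * rate / spec$baseline_hazard
  }
  lam
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]. Planted genes are bimodal in
#' log2 space (two-component Gaussian mixture, components centred two
#' noise-SDs either side of the threshold, so the split is learnable with
#' a gap); all other genes are drawn independently of survival around
#' gene-specific baseline means. Each sample's failure time is
#' exponential with the hazard implied by its planted-gene sides; the
#' observed time is the minimum of the failure and a uniform
#' administrative-censoring draw. Recurrence-free analogues use the
#' "recurrence or death, whichever first" rule.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `nr_cohort` with `tumor_expression` (and
#'   `normal_expression` if requested), `clinical` (tibble with survival,
#'   recurrence and demographic covariates, the latter independent of
#'   survival), `truth` (per-sample planted risk class and hazards) and
#'   the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "nr_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  G <- spec$n_genes
  samples <- sprintf("s%03d", seq_len(n))
  genes <- sprintf("g%03d", seq_len(G))

  gene_means <- stats::rnorm(G, mean = -6, sd = 2)
  expr <- matrix(stats::rnorm(G * n, mean = gene_means, sd = spec$noise_sd),
                 nrow = G, ncol = n, dimnames = list(genes, samples))

  pg <- spec$planted_genes
  planted_idx <- if (!is.null(pg) && nrow(pg)) unique(pg$gene) else integer()
  sides <- matrix(FALSE, n, length(planted_idx),
                  dimnames = list(samples, as.character(planted_idx)))
  if (length(planted_idx)) {
    # one side draw per component; co-expressed genes share it
    comp_ids <- unique(pg$component)
    comp_below <- lapply(comp_ids, function(cc) stats::runif(n) < 0.5)
    names(comp_below) <- as.character(comp_ids)
  }
  for (j in seq_along(planted_idx)) {
    gi <- planted_idx[j]
    row <- match(gi, pg$gene)
    thr <- pg$threshold[row]
    below <- comp_below[[as.character(pg$component[row])]]
    centre <- ifelse(below, thr - 2 * spec$noise_sd, thr + 2 * spec$noise_sd)
    expr[gi, ] <- stats::rnorm(n, centre, spec$noise_sd)
    # noise can cross the threshold; the realized side defines the truth
    sides[, j] <- expr[gi, ] < thr
  }

  lam_os <- planted_hazard(spec, "os", sides)
  lam_rfs_extra <- planted_hazard(spec, "rfs", sides)

  horizon <- spec$censor_horizon
  if (!is.null(spec$admin_censor_frac_target)) {
    classes <- unique(lam_os)
    # expected class weights: each planted side is an independent fair coin
    wts <- vapply(classes, function(l) {
      expected_class_weight(spec, l)
    }, numeric(1))
    horizon <- calibrate_horizon(classes, wts / sum(wts),
                                 spec$admin_censor_frac_target)
  }

  t_fail <- stats::rexp(n, rate = lam_os)
  t_cens <- stats::runif(n, 0, horizon)
  os_time <- pmin(t_fail, t_cens)
  os_event <- as.integer(t_fail <= t_cens)

  t_recur <- stats::rexp(n, rate = lam_rfs_extra)
  rfs_time <- pmin(t_recur, os_time)
  rfs_event <- as.integer(pmin(t_recur, t_fail) <= t_cens)

  clinical <- tibble::tibble(
    sample_id = samples,
    os_time = pmax(os_time, 1e-3), os_event = os_event,
    rfs_time = pmax(rfs_time, 1e-3), rfs_event = rfs_event,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.57, 0.13, 0.17, 0.13)),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.52, 0.48)),
    age = round(stats::rnorm(n, 63, 8)),
    histology = sample(c("ADC", "SCC"), n, replace = TRUE,
                       prob = c(0.73, 0.27)),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.14, 0.5, 0.36)),
    adjuvant_chemo = stats::rbinom(n, 1, 0.12),
    adjuvant_rt = stats::rbinom(n, 1, 0.08))

  risk_class <- rep("low", n)
  if (length(planted_idx)) {
    os_pg <- pg[pg$endpoint == "os", , drop = FALSE]
    primary <- if (nrow(os_pg)) os_pg[1L, ] else pg[1L, ]
    below <- sides[, as.character(primary$gene)]
    high_side_below <- primary$rate_below >= primary$rate_above
    risk_class <- ifelse(below == high_side_below, "high", "low")
  }
  truth <- tibble::tibble(sample_id = samples, risk_class = risk_class,
                          hazard_os = lam_os, hazard_rfs = lam_rfs_extra)

  normal <- NULL
  if (!is.null(spec$paired_normal_corr)) {
    normal <- correlated_partner(expr, spec$paired_normal_corr)
  }
  tumor <- expr
  if (spec$planted_tissue == "normal" && !is.null(normal)) {
    tmp <- tumor; tumor <- normal; normal <- tmp
  }
  if (spec$platform == "microarray") {
    tumor <- compress_dynamic_range(tumor)
    if (!is.null(normal)) normal <- compress_dynamic_range(normal)
  }

  structure(list(tumor_expression = tumor, normal_expression = normal,
                 clinical = clinical, truth = truth, spec = spec,
                 censor_horizon_used = horizon),
            class = "nr_cohort")
}

expected_class_weight <- function(spec, lambda) {
  pg <- spec$planted_genes
  pg <- pg[pg$endpoint == "os", , drop = FALSE]
  if (!nrow(pg)) return(1)
  comps <- unique(pg$component)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(comps)))
  w <- 0
  for (r in seq_len(nrow(combos))) {
    lam <- spec$baseline_hazard
    for (k in seq_len(nrow(pg))) {
      below <- combos[r, match(pg$component[k], comps)]
      rate <- if (below) pg$rate_below[k] else pg$rate_above[k]
      lam <- lam * rate / spec$baseline_hazard
    }
    if (abs(lam - lambda) < 1e-12) w <- w + 0.5^length(comps)
  }
  w
}

# Paired-tissue partner matrix achieving (in expectation) the requested
# pooled Pearson correlation with the source matrix.
correlated_partner <- function(mat, rho) {
  v <- as.vector(mat)
  z <- stats::rnorm(length(v), 0, stats::sd(v))
  out <- mean(v) + rho * (v - mean(v)) + sqrt(1 - rho^2) * z
  matrix(out, nrow = nrow(mat), dimnames = dimnames(mat))
}

# Microarray emulation: compressed dynamic range plus platform noise.
compress_dynamic_range <- function(mat, factor = 0.4, extra_sd = 0.3) {
  m <- mean(mat)
  m + factor * (mat - m) +
    matrix(stats::rnorm(length(mat), 0, extra_sd), nrow = nrow(mat))
}

#' Append survival-independent genes to a cohort
#'
#' Extends a planted cohort with `n_null_genes` additional genes drawn
#' independently of survival, producing the genome-wide background needed
#' for random-gene-set permutation analyses. The original cohort
#' (expression, clinical table, truth) is unchanged; with
#' `n_null_genes = 0` the result is identical to [generate_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param n_null_genes Number of null genes to append.
#' @return An `nr_cohort` whose tumor matrix has
#'   `spec$n_genes + n_null_genes` rows.
#' @export
generate_genomewide <- function(spec, n_null_genes) {
  cohort <- generate_cohort(spec)
  if (n_null_genes == 0) return(cohort)
  n <- spec$n_patients
  genes <- sprintf("null%05d", seq_len(n_null_genes))
  means <- stats::rnorm(n_null_genes, -6, 2)
  extra <- matrix(stats::rnorm(n_null_genes * n, means, spec$noise_sd),
                  nrow = n_null_genes,
                  dimnames = list(genes, colnames(cohort$tumor_expression)))
  if (spec$platform == "microarray") extra <- compress_dynamic_range(extra)
  cohort$tumor_expression <- rbind(cohort$tumor_expression, extra)
  cohort
}

#' Write a cohort to plain-text artifacts
#'
#' Writes the tumor (and, if present, normal) expression matrix as TSV
#' (rows = genes, columns = samples, log2 values), the clinical table as
#' CSV, and the generating spec plus per-sample truth as JSON.
#'
#' @param cohort An `nr_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$tumor_expression, paths["expression"])
  if (!is.null(cohort$normal_expression)) {
    paths["normal"] <- file.path(dir, "expression_normal.tsv")
    write_expression(cohort$normal_expression, paths["normal"])
  }
  readr::write_csv(cohort$clinical, paths["clinical"])
  spec <- cohort$spec
  spec$planted_genes <- as.data.frame(spec$planted_genes)
  jsonlite::write_json(list(spec = unclass(spec),
                            truth = cohort$truth,
                            censor_horizon_used = cohort$censor_horizon_used),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
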