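#' Bundle expression and clinical data for analysis
#'
#' Aligns a genes x samples expression matrix with a clinical table and
#' fixes the survival endpoint used by the modelling functions. Samples
#' present in only one of the two inputs are an error.
#'
#' @param expression Genes x samples numeric matrix (log2 scale) with
#'   sample column names.
#' @param clinical Data frame with `sample_id` and the endpoint columns
#'   (`os_time`/`os_event`, and `rfs_time`/`rfs_event` if the
#'   recurrence-free endpoint is used).
#' @param platform Free-text platform tag (e.g. "qpcr", "microarray").
#' @param endpoint "os" (overall survival, default) or "rfs"
#'   (recurrence-free).
#' @param normal_expression Optional paired normal-tissue matrix with the
#'   same dimensions and sample names.
#' @return A list of class `nr_dataset` with the matrix, the clinical
#'   tibble (reordered to the matrix columns), and `time`/`event` vectors
#'   for the chosen endpoint.
#' @export
nr_dataset <- function(expression, clinical, platform = "qpcr",
                       endpoint = c("os", "rfs"),
                       normal_expression = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.matrix(expression), !is.null(colnames(expression)),
            "sample_id" %in% names(clinical))
  missing <- setdiff(colnames(expression), clinical$sample_id)
  if (length(missing)) {
    stop("samples without clinical records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ]
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical))) {
    stop("clinical table lacks ", tcol, "/", ecol, call. = FALSE)
  }
  check_surv(clinical[[tcol]], clinical[[ecol]])
  structure(list(expression = expression, clinical = tibble::as_tibble(clinical),
                 platform = platform, endpoint = endpoint,
                 time = clinical[[tcol]], event = clinical[[ecol]],
                 normal_expression = normal_expression),
            class = "nr_dataset")
}

#' Convert a synthetic cohort to an analysis dataset
#'
#' @param cohort An `nr_cohort` from [generate_cohort()].
#' @param endpoint Survival endpoint, as in [nr_dataset()].
#' @param tissue Which expression matrix to analyse.
#' @return An `nr_dataset`.
#' @export
as_dataset <- function(cohort, endpoint = c("os", "rfs"),
                       tissue = c("tumor", "normal")) {
  endpoint <- match.arg(endpoint)
  tissue <- match.arg(tissue)
  expr <- if (tissue == "tumor") cohort$tumor_expression else {
    if (is.null(cohort$normal_expression)) {
      stop("cohort has no normal-tissue matrix", call. = FALSE)
    }
    cohort$normal_expression
  }
  nr_dataset(expr, cohort$clinical, platform = cohort$spec$platform,
             endpoint = endpoint,
             normal_expression = cohort$normal_expression)
}

#' Read a gene x sample expression TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' numeric log2 values. Duplicate gene rows (e.g. several probe sets for
#' the same gene) are collapsed by their mean.
#'
#' @param path Path to the TSV file.
#' @return Genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty or malformed expression file: ", path, call. = FALSE)
  }
  gene <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(vals)
  rownames(mat) <- gene
  if (anyDuplicated(gene)) mat <- collapse_probes(mat)
  mat
}

#' Collapse duplicate gene rows by their mean
#'
#' Probe-to-gene collapse: rows sharing a gene id are replaced by their
#' columnwise average. Row order follows first appearance.
#'
#' @param mat Genes x samples matrix, row names possibly duplicated.
#' @return Matrix with unique row names.
#' @export
collapse_probes <- function(mat) {
  genes <- unique(rownames(mat))
  out <- t(vapply(genes, function(g) {
    colMeans(mat[rownames(mat) == g, , drop = FALSE])
  }, numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  out
}

#' Write an expression matrix as TSV
#'
#' @param mat Genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and validate a clinical CSV
#'
#' Requires `sample_id`, `os_time` and `os_event`. When `rfs_time` /
#' `rfs_event` are absent but recurrence components are present
#' (`recurrence_time`, `recurrence_event`), the recurrence-free endpoint
#' is derived as time to recurrence or death, whichever comes first, with
#' censoring at the observed survival time otherwise.
#'
#' @param path Path to the CSV file.
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_surv(df$os_time, df$os_event)
  if (!all(c("rfs_time", "rfs_event") %in% names(df)) &&
      all(c("recurrence_time", "recurrence_event") %in% names(df))) {
    df <- derive_rfs(df)
  }
  if ("stage" %in% names(df) &&
      !all(df$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage values must be I/II/III/IV", call. = FALSE)
  }
  tibble::as_tibble(df)
}

# rfs = recurrence or death, whichever first; otherwise censored at the
# last observed survival time.
derive_rfs <- function(df) {
  has_rec <- !is.na(df$recurrence_time) & df$recurrence_event == 1
  rec_first <- has_rec & df$recurrence_time <= df$os_time
  df$rfs_time <- ifelse(rec_first, df$recurrence_time, df$os_time)
  df$rfs_event <- as.integer(rec_first | df$os_event == 1)
  df
}

#' Write a Kaplan-Meier curve as TSV
#'
#' @param km An `nr_km` object from [km_fit()].
#' @param path Output path.
#' @export
write_km_tsv <- function(km, path) {
  readr::write_tsv(tibble::as_tibble(km), path)
  invisible(path)
}

#' Serialize an analysis result to JSON
#'
#' Validation results, permutation nulls, trees, and plain lists are
#' written with their configuration and seeds embedded so a run can be
#' reproduced from its output.
#'
#' @param x Result object.
#' @param path Output path.
#' @export
write_results_json <- function(x, path) {
  payload <- result_payload(x)
  payload$software <- list(package = "nrprog",
                           version = as.character(utils::packageVersion("nrprog")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

result_payload <- function(x) {
  if (inherits(x, "nr_validation")) {
    list(type = "validation", labels = x$labels,
         logrank_p = x$logrank_p, hr = x$hr, hr_ci = x$hr_ci,
         cox_p = x$cox_p, n_high = x$n_high, n_low = x$n_low,
         degenerate = x$degenerate, harmonization = x$harmonization)
  } else if (inherits(x, "nr_permnull")) {
    list(type = "permutation_null", n_sets = x$n_sets,
         n_valid = x$n_valid, reference_p = x$reference_p,
         empirical_p = x$empirical_p, seed = x$seed, pvalues = x$pvalues)
  } else if (inherits(x, "nr_survtree")) {
    list(type = "survival_tree", nodes = tree_skeleton(x),
         cp_table = x$cp_table, cp_chosen = x$cp_chosen %||% NA)
  } else {
    as.list(x)
  }
}
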