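#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.nr_cox <- function(x, ...) x$coefficients

#' @export
glance.nr_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik_null = unname(x$loglik["null"]),
                 loglik = unname(x$loglik["fitted"]),
                 score_statistic = x$score_statistic,
                 score_p = x$score_p, iterations = x$iterations,
                 converged = x$converged, infinite_beta = x$infinite_beta,
                 ties = x$ties)
}

#' @export
tidy.nr_survtree <- function(x, ...) {
  dplyr::bind_rows(lapply(x$nodes, function(nd) {
    if (!node_reachable(x, nd$id)) return(NULL)
    tibble::tibble(node = nd$id, n = nd$n, events = nd$events,
                   exposure = nd$exposure, rate = nd$rate,
                   deviance = nd$deviance, is_leaf = nd$is_leaf,
                   gene = nd$gene, threshold = nd$threshold)
  }))
}

#' @export
glance.nr_survtree <- function(x, ...) {
  tb <- tidy(x)
  tibble::tibble(n = x$nodes[[x$root]]$n,
                 n_events = x$nodes[[x$root]]$events,
                 n_leaves = sum(tb$is_leaf),
                 n_splits = sum(!tb$is_leaf),
                 genes_used = paste(tree_genes(x), collapse = ","),
                 cp_chosen = x$cp_chosen %||% NA_real_)
}

#' @export
tidy.nr_validation <- function(x, ...) x$labels

#' @export
glance.nr_validation <- function(x, ...) {
  tibble::tibble(n = nrow(x$labels), n_high = x$n_high, n_low = x$n_low,
                 logrank_p = x$logrank_p, hr = x$hr,
                 hr_conf.low = x$hr_ci[1], hr_conf.high = x$hr_ci[2],
                 cox_p = x$cox_p, cox_flagged = isTRUE(x$cox_flagged),
                 degenerate = x$degenerate)
}

#' @export
tidy.nr_permnull <- function(x, ...) {
  tibble::tibble(set = seq_along(x$pvalues), p.value = x$pvalues)
}

#' @export
glance.nr_permnull <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, n_valid = x$n_valid,
                 reference_p = x$reference_p, empirical_p = x$empirical_p,
                 seed = x$seed)
}

#' @export
tidy.nr_km <- function(x, ...) tibble::as_tibble(x)

#' @export
print.nr_validation <- function(x, ...) {
  cat("Risk-group validation\n")
  if (x$degenerate) {
    cat("  degenerate: all", nrow(x$labels), "samples in one risk group\n")
  } else {
    cat(sprintf("  high/low: %d/%d, log-rank p = %.3g\n",
                x$n_high, x$n_low, x$logrank_p))
    cat(sprintf("  Cox HR (high vs low): %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
                x$hr, x$hr_ci[1], x$hr_ci[2], x$cox_p,
                if (isTRUE(x$cox_flagged))
                  " [flagged: monotone likelihood]" else ""))
  }
  invisible(x)
}

#' @export
print.nr_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards model (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(x$coefficients)
  invisible(x)
}

#' Kaplan-Meier step plot
#'
#' @param object An `nr_km` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot object: one step curve per group with censor marks.
#' @export
autoplot.nr_km <- function(object, ...) {
  df <- tibble::as_tibble(object)
  has_group <- "group" %in% names(df)
  if (!has_group) df$group <- "all"
  start <- dplyr::distinct(df, .data$group)
  start$time <- 0; start$estimate <- 1; start$n_censor <- 0
  df2 <- dplyr::bind_rows(start, df[, names(start)])
  p <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$time, y = .data$estimate,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$n_censor > 0, ], shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!has_group) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Kaplan-Meier plot of a validation result
#'
#' @param object An `nr_validation`.
#' @param ... Unused.
#' @return A ggplot of the predicted high- vs low-risk curves annotated
#'   with the log-rank p-value.
#' @export
autoplot.nr_validation <- function(object, ...) {
  if (object$degenerate || is.null(object$km)) {
    stop("degenerate validation result: nothing to plot", call. = FALSE)
  }
  autoplot(object$km) +
    ggplot2::labs(subtitle = sprintf("log-rank p = %.3g, HR = %.2f",
                                     object$logrank_p, object$hr))
}

#' Histogram of a permutation null
#'
#' @param object An `nr_permnull`.
#' @param ... Unused.
#' @return A ggplot histogram of the random-set p-values with the
#'   reference level marked.
#' @export
autoplot.nr_permnull <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$p.value), ],
                  ggplot2::aes(x = .data$p.value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$reference_p,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "log-rank p of random gene set", y = "count",
                  subtitle = sprintf("empirical p = %.3g (%d/%d sets)",
                                     object$empirical_p,
                                     sum(df$p.value <= object$reference_p,
                                         na.rm = TRUE),
                                     object$n_valid)) +
    ggplot2::theme_minimal()
}

#' Empirical CDF comparison plot for p-value distributions
#'
#' @param cmp Result of [pvalue_cdf_compare()].
#' @return A ggplot of the two empirical CDFs.
#' @export
plot_pvalue_cdf <- function(cmp) {
  ggplot2::ggplot(cmp$cdf, ggplot2::aes(x = .data$p, y = .data$cdf,
                                        colour = .data$source)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "univariate Cox p-value", y = "cumulative fraction",
                  colour = NULL,
                  subtitle = sprintf("KS p = %.3g", cmp$ks$p.value)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
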