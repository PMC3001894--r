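#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival-curve estimate under right censoring,
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event
#' times. Censored subjects leave the risk set without contributing a
#' step.
#'
#' @param data Data frame with one row per subject.
#' @param time,event Column names (strings) of the follow-up time (> 0)
#'   and the event indicator (0 = censored, 1 = event).
#' @param group Optional column name of a grouping factor; when given the
#'   curve is estimated within each group.
#' @return An object of class `nr_km`: a tibble with columns `group`
#'   (if requested), `time`, `n_risk`, `n_event`, `n_censor`, `estimate`,
#'   one row per distinct observed time.
#' @export
km_fit <- function(data, time = "time", event = "event", group = NULL) {
  tt <- data[[time]]
  ev <- data[[event]]
  check_surv(tt, ev)
  if (is.null(group)) {
    out <- km_curve(tt, ev)
  } else {
    g <- data[[group]]
    out <- dplyr::bind_rows(lapply(split(seq_along(tt), g), function(idx) {
      dplyr::mutate(km_curve(tt[idx], ev[idx]), group = g[idx[1]],
                    .before = 1)
    }))
  }
  class(out) <- c("nr_km", class(out))
  out
}

km_curve <- function(time, event) {
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  est <- cumprod(1 - n_event / n_risk)
  tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, estimate = est)
}

check_surv <- function(time, event) {
  if (length(time) < 1L) stop("empty survival data", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-rank test for K groups
#'
#' Observed-minus-expected event counts at each distinct event time, with
#' hypergeometric variance, summed into a chi-square statistic on K - 1
#' degrees of freedom.
#'
#' @inheritParams km_fit
#' @param group Column name of the group labels; at least two nonempty
#'   groups.
#' @return A list of class `nr_logrank` with `statistic`, `df`,
#'   `p.value`, and the per-group observed/expected table `obs_exp`.
#' @export
logrank_test <- function(data, time = "time", event = "event",
                         group = "group") {
  tt <- data[[time]]
  ev <- data[[event]]
  g <- as.factor(data[[group]])
  check_surv(tt, ev)
  g <- droplevels(g)
  K <- nlevels(g)
  if (K < 2L) stop("log-rank test needs at least two groups", call. = FALSE)
  ut <- sort(unique(tt[ev == 1]))
  O <- E <- stats::setNames(numeric(K), levels(g))
  V <- matrix(0, K, K, dimnames = list(levels(g), levels(g)))
  for (t in ut) {
    at_risk <- tt >= t
    n <- sum(at_risk)
    d <- sum(tt == t & ev == 1)
    ng <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dg <- vapply(levels(g), function(l) sum(tt == t & ev == 1 & g == l),
                 numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      V <- V + mult * (diag(ng / n, K) - (ng / n) %o% (ng / n))
    }
  }
  u <- (O - E)[-K]
  Vsub <- V[-K, -K, drop = FALSE]
  stat <- if (all(abs(u) < 1e-12)) 0 else {
    as.numeric(t(u) %*% solve(Vsub, u))
  }
  structure(list(statistic = stat, df = K - 1L,
                 p.value = stats::pchisq(stat, K - 1L, lower.tail = FALSE),
                 obs_exp = tibble::tibble(group = levels(g), observed = O,
                                          expected = E)),
            class = "nr_logrank")
}

#' Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the Cox partial likelihood, with the
#' Efron (default) or Breslow correction for tied event times. Reports
#' per-covariate coefficients, hazard ratios with Wald 95% confidence
#' intervals and p-values, the score test at beta = 0, and convergence
#' diagnostics. A monotone partial likelihood (complete separation) is
#' flagged via `infinite_beta` rather than returned as a silent number.
#'
#' @param data Data frame with one row per subject.
#' @param covariates Character vector of covariate column names; none may
#'   be constant, and n must exceed the number of covariates.
#' @param time,event Survival column names as in [km_fit()].
#' @param ties Tie handling, "efron" (default) or "breslow".
#' @return An object of class `nr_cox` with elements `coefficients`
#'   (tibble: term, estimate, std.error, statistic, p.value, hr,
#'   conf.low, conf.high), `loglik` (null and fitted), `score_statistic`,
#'   `score_p`, `iterations`, `converged`, `infinite_beta`, `n`,
#'   `n_events`, `ties`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  tt <- data[[time]]
  ev <- data[[event]]
  check_surv(tt, ev)
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (nrow(X) <= ncol(X)) stop("need more subjects than covariates")
  const <- apply(X, 2, function(x) max(x) - min(x)) == 0
  if (any(const)) {
    stop("constant covariate(s): ", paste(covariates[const], collapse = ", "),
         call. = FALSE)
  }
  fit <- cox_engine(X, tt, ev, ties)
  fit$beta <- unname(fit$beta)
  se <- unname(sqrt(diag(fit$var)))
  z <- fit$beta / se
  coef_tbl <- tibble::tibble(
    term = covariates,
    estimate = fit$beta,
    std.error = se,
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z)),
    hr = exp(fit$beta),
    conf.low = exp(fit$beta - stats::qnorm(0.975) * se),
    conf.high = exp(fit$beta + stats::qnorm(0.975) * se)
  )
  structure(list(coefficients = coef_tbl, loglik = fit$loglik,
                 score_statistic = fit$score_stat, score_p = fit$score_p,
                 iterations = fit$iter, converged = fit$converged,
                 infinite_beta = fit$infinite, n = nrow(X),
                 n_events = sum(ev), ties = ties),
            class = "nr_cox")
}

# Partial likelihood, gradient and information at a given beta.
cox_loglik <- function(beta, X, time, event, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  event_times <- sort(unique(time[event == 1]))
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in event_times) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    sw_r <- sum(w[risk])
    swx_r <- colSums(X[risk, , drop = FALSE] * w[risk])
    swxx_r <- crossprod(X[risk, , drop = FALSE] * sqrt(w[risk]))
    ll <- ll + sum(eta[dead])
    U <- U + colSums(X[dead, , drop = FALSE])
    if (ties == "efron" && d > 1) {
      sw_d <- sum(w[dead])
      swx_d <- colSums(X[dead, , drop = FALSE] * w[dead])
      swxx_d <- crossprod(X[dead, , drop = FALSE] * sqrt(w[dead]))
      for (j in seq_len(d) - 1L) {
        phi <- j / d
        denom <- sw_r - phi * sw_d
        xbar <- (swx_r - phi * swx_d) / denom
        ll <- ll - log(denom)
        U <- U - xbar
        I <- I + (swxx_r - phi * swxx_d) / denom - xbar %o% xbar
      }
    } else {
      xbar <- swx_r / sw_r
      ll <- ll - d * log(sw_r)
      U <- U - d * xbar
      I <- I + d * (swxx_r / sw_r - xbar %o% xbar)
    }
  }
  list(loglik = ll, gradient = U, information = I)
}

cox_engine <- function(X, time, event, ties, max_iter = 30, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  at0 <- cox_loglik(beta, X, time, event, ties)
  score_stat <- tryCatch(
    as.numeric(t(at0$gradient) %*% solve(at0$information, at0$gradient)),
    error = function(e) NA_real_)
  ll0 <- at0$loglik
  cur <- at0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$information, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new <- cox_loglik(new_beta, X, time, event, ties)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik - 1e-12) &&
           halvings < 10L) {   # step halving keeps the likelihood ascending
      new_beta <- (beta + new_beta) / 2
      new <- cox_loglik(new_beta, X, time, event, ties)
      halvings <- halvings + 1L
    }
    done <- abs(new$loglik - cur$loglik) < tol
    beta <- new_beta
    cur <- new
    if (done) { converged <- TRUE; break }
  }
  infinite <- any(abs(beta) > 15)
  if (infinite) {
    warning("monotone partial likelihood: coefficient diverging ",
            "(complete separation); estimates unreliable", call. = FALSE)
  }
  var <- tryCatch(solve(cur$information), error = function(e) {
    matrix(NA_real_, p, p)
  })
  list(beta = beta, var = var, loglik = c(null = ll0, fitted = cur$loglik),
       score_stat = score_stat,
       score_p = stats::pchisq(score_stat, p, lower.tail = FALSE),
       iter = iter, converged = converged, infinite = infinite)
}

#' Per-gene univariate Cox scan
#'
#' Fits one single-covariate Cox model per gene of an expression matrix
#' and reports the hazard ratio and Wald p-value of each, together with
#' the empirical distribution of p-values (useful for comparing a gene
#' family against random gene sets).
#'
#' @param expr Genes x samples numeric matrix (log2 scale); sample columns
#'   must align with the rows of `data`.
#' @param data Clinical data frame with the survival columns.
#' @param time,event,ties As in [cox_fit()].
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. "BH"); default "none", matching the
#'   convention of reporting raw univariate p-values.
#' @return A tibble with columns `gene`, `estimate`, `hr`, `p.value`,
#'   `flag` (fit warnings, if any) and, when `adjust != "none"`,
#'   `p.adjusted`.
#' @export
univariate_scan <- function(expr, data, time = "time", event = "event",
                            ties = "efron", adjust = "none") {
  stopifnot(nrow(expr) >= 1L, ncol(expr) == nrow(data))
  rows <- lapply(rownames(expr) %||% as.character(seq_len(nrow(expr))),
                 function(g) g)
  scan_one <- function(i) {
    d <- data.frame(x = expr[i, ], t = data[[time]], e = data[[event]])
    flag <- NA_character_
    fit <- withCallingHandlers(
      tryCatch(cox_fit(d, "x", time = "t", event = "e", ties = ties),
               error = function(e) {
                 flag <<- conditionMessage(e)
                 NULL
               }),
      warning = function(w) {
        flag <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    if (is.null(fit)) {
      return(tibble::tibble(gene = rows[[i]], estimate = NA_real_,
                            hr = NA_real_, p.value = NA_real_, flag = flag))
    }
    co <- fit$coefficients
    tibble::tibble(gene = rows[[i]], estimate = co$estimate, hr = co$hr,
                   p.value = co$p.value, flag = flag)
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(expr)), scan_one))
  if (adjust != "none") out$p.adjusted <- stats::p.adjust(out$p.value, adjust)
  out
}

#' Exact test on a 2 x K contingency table
#'
#' Two-sided Fisher exact test using the probability-ordering convention:
#' the p-value is the total conditional (multivariate hypergeometric)
#' probability, over all tables with the observed margins, of tables no
#' more probable than the observed one. K = 2 uses the hypergeometric
#' distribution directly; K > 2 enumerates all tables with the observed
#' margins (feasible at cohort scale).
#'
#' @param table A 2 x K matrix of nonnegative integer counts, K >= 2.
#' @return The two-sided p-value.
#' @export
fisher_exact_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L) stop("need a 2 x K table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  col_tot <- colSums(table)
  keep <- col_tot > 0
  table <- table[, keep, drop = FALSE]
  K <- ncol(table)
  if (K < 2L) return(1)
  r1 <- sum(table[1L, ])
  N <- sum(table)
  reltol <- 1 + 1e-7
  if (K == 2L) {
    m <- sum(table[, 1L])
    support <- max(0L, r1 - (N - m)):min(r1, m)
    probs <- stats::dhyper(support, m, N - m, r1)
    p_obs <- stats::dhyper(table[1L, 1L], m, N - m, r1)
    return(min(1, sum(probs[probs <= p_obs * reltol])))
  }
  cj <- colSums(table)
  log_denom <- lchoose(N, r1)
  log_p <- function(a) sum(lchoose(cj, a)) - log_denom
  p_obs <- log_p(table[1L, ])
  total <- 0
  recurse <- function(j, remaining, acc_logp) {
    if (j == K) {
      if (remaining <= cj[K]) {
        lp <- acc_logp + lchoose(cj[K], remaining) - log_denom
        if (lp <= p_obs + log(reltol)) total <<- total + exp(lp)
      }
      return(invisible())
    }
    lo <- max(0L, remaining - sum(cj[(j + 1L):K]))
    hi <- min(cj[j], remaining)
    for (a in lo:hi) {
      recurse(j + 1L, remaining - a, acc_logp + lchoose(cj[j], a))
    }
  }
  recurse(1L, r1, 0)
  min(1, total)
}

#' Welch two-sample t test from group summaries
#'
#' Welch statistic with Satterthwaite degrees of freedom computed from
#' per-group means, standard errors and sizes, for the common situation
#' where only summary statistics (mean +/- SE) are reported.
#'
#' @param mean1,se1,n1 Mean, standard error of the mean, and size of
#'   group 1.
#' @param mean2,se2,n2 Likewise for group 2.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
welch_t_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (se1 == 0 && se2 == 0) stop("zero variance in both groups")
  v <- se1^2 + se2^2
  stat <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  tibble::tibble(statistic = stat, df = df,
                 p.value = 2 * stats::pt(-abs(stat), df))
}

#' Welch two-sample t test on raw vectors
#'
#' @param x,y Raw observations per group (n >= 2 each).
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(x, y)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
}

#' Paired t test
#'
#' One-sample t test on within-pair differences (e.g. tumor vs adjacent
#' normal expression of the same patient).
#'
#' @param x,y Paired observations, equal length >= 2.
#' @return A tibble with `statistic`, `df`, `p.value`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  ht <- stats::t.test(d)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value,
                 mean_difference = mean(d))
}

#' Pearson correlation with t-approximation p-value
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A tibble with `r`, `statistic`, `df`, `p.value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the empirical CDFs of two samples (typically two
#' collections of p-values), with the asymptotic p-value.
#'
#' @param a,b Nonempty numeric samples.
#' @return A tibble with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ht <- suppressWarnings(stats::ks.test(a, b))
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
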