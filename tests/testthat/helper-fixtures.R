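# Shared fixtures, built in code at test time.

# Cohort with one strongly separable planted gene: hazard 0.5 vs 0.01
# events/month across a clean bimodal gap. Conditions under which the
# tree method is expected to recover the planted gene reliably.
separable_spec <- function(seed, n = 30, n_genes = 48,
                           rate_below = 0.5, rate_above = 0.01,
                           gene = 1L, threshold = -8.5, endpoint = "os",
                           paired_normal_corr = NULL, ...) {
  cohort_spec(n_patients = n, n_genes = n_genes,
              planted_genes = tibble::tibble(gene = gene,
                                             threshold = threshold,
                                             rate_below = rate_below,
                                             rate_above = rate_above,
                                             endpoint = endpoint),
              censor_horizon = 60,
              paired_normal_corr = paired_normal_corr,
              seed = seed, ...)
}

null_spec <- function(seed, n = 30, n_genes = 48, ...) {
  cohort_spec(n_patients = n, n_genes = n_genes, planted_genes = NULL,
              paired_normal_corr = NULL, seed = seed, ...)
}

# Small survival data frame builder.
surv_df <- function(time, event, ...) {
  data.frame(time = time, event = event, ...)
}

# Independent partial log-likelihood for a single covariate with no tied
# event times (grid-search oracle for cox_fit).
pl_untied <- function(beta, x, time, event) {
  eta <- beta * x
  sum(vapply(which(event == 1), function(i) {
    eta[i] - log(sum(exp(eta[time >= time[i]])))
  }, numeric(1)))
}

# Brute-force average-linkage clustering oracle: recompute the full mean
# pairwise distance between every cluster pair at every merge.
avg_link_oracle <- function(expr) {
  d0 <- as.matrix(stats::dist(t(expr)))
  clusters <- lapply(seq_len(ncol(expr)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dd < best[1] - 1e-12) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# Exhaustive best-split oracle: every gene x midpoint threshold,
# deviance reduction computed from first principles (per-subject Poisson
# deviance terms), same admissibility and tie-break rules as grow().
best_split_oracle <- function(expr, d, t, minbucket) {
  dev_side <- function(sel) {
    Tt <- sum(t[sel]); D <- sum(d[sel])
    if (D == 0) return(0)
    lam <- D / Tt
    sum(2 * (ifelse(d[sel] == 1, log(1 / (lam * t[sel])), 0) -
               (d[sel] - lam * t[sel])))
  }
  parent <- dev_side(rep(TRUE, length(d)))
  best <- NULL
  for (gi in seq_len(nrow(expr))) {
    v <- expr[gi, ]
    for (th in sort(unique(v))[-1]) {
      cut <- (th + max(v[v < th])) / 2
      left <- v < cut
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      red <- parent - dev_side(left) - dev_side(!left)
      if (is.null(best) || red > best$reduction + 1e-10) {
        best <- list(gene = gi, threshold = cut, reduction = red)
      }
    }
  }
  best
}
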