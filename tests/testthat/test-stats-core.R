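test_that("product-limit estimator matches hand-computed risk tables", {
  km <- km_fit(surv_df(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  cens <- km_fit(surv_df(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(cens$estimate == 1))

  # middle subject censored: S = 2/3 after t=1, 0 after t=3
  mid <- km_fit(surv_df(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(mid$estimate, c(2 / 3, 2 / 3, 0))

  # mass conservation: S at the last event time is exactly the product
  set.seed(5)
  tt <- round(stats::rexp(40, 0.1), 2) + 0.01
  ev <- stats::rbinom(40, 1, 0.6)
  km2 <- km_fit(surv_df(tt, ev))
  expect_identical(km2$estimate, cumprod(1 - km2$n_event / km2$n_risk))
  expect_true(all(km2$estimate >= 0 & km2$estimate <= 1))
  expect_true(all(diff(km2$estimate) <= 0))
  expect_error(km_fit(surv_df(numeric(), numeric())), "empty")
})

test_that("product-limit estimator agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(6)
  d <- surv_df(stats::rexp(60, 0.05) + 0.01, stats::rbinom(60, 1, 0.5))
  km <- km_fit(d)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1, d),
                times = km$time)
  expect_equal(km$estimate, sf$surv, tolerance = 1e-12)
})

test_that("log-rank test matches a by-hand observed-minus-expected table", {
  same <- surv_df(rep(c(1, 2, 3), 2), rep(1, 6),
                  group = rep(c("a", "b"), each = 3))
  res <- logrank_test(same)
  expect_identical(res$statistic, 0)
  expect_identical(res$p.value, 1)

  # A events at 1,2; B events at 3,4: hand risk table
  d <- surv_df(c(1, 2, 3, 4), c(1, 1, 1, 1),
               group = c("a", "a", "b", "b"))
  # by hand: t=1 (nA=2,n=4,d=1): E_A=.5 V=.25; t=2 (1/3): E_A=1/3 V=2/9;
  # t=3 (0/2): E_A=0; t=4: single subject, no variance
  O_A <- 2; E_A <- 0.5 + 1 / 3; V <- 0.25 + 2 / 9
  expect_equal(logrank_test(d)$statistic, (O_A - E_A)^2 / V)

  expect_error(logrank_test(surv_df(1:3, c(1, 1, 1), group = "a")),
               "two groups")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(7)
  d <- surv_df(stats::rexp(24, 0.1) + 0.01, stats::rbinom(24, 1, 0.7))
  ps <- replicate(1000, {
    d$group <- sample(rep(c("a", "b"), each = 12))
    logrank_test(d)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Cox fit maximises the partial likelihood (grid oracle) and is
          calibrated", {
  set.seed(8)
  n <- 20
  x <- stats::rbinom(n, 1, 0.5)
  tt <- stats::rexp(n, 0.05 * exp(0.9 * x))
  d <- surv_df(tt, rep(1, n), x = x)  # continuous times: no ties
  fit <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 1e-4)
  pls <- vapply(grid, pl_untied, numeric(1), x = x, time = tt,
                event = rep(1, n))
  expect_equal(fit$coefficients$estimate, grid[which.max(pls)],
               tolerance = 1.1e-4)
  expect_true(fit$converged)
  expect_true(fit$coefficients$conf.low < fit$coefficients$hr &
                fit$coefficients$hr < fit$coefficients$conf.high)

  # a covariate carrying no signal: HR near 1
  set.seed(9)
  d0 <- surv_df(stats::rexp(200, 0.1), rep(1, 200),
                x = stats::rbinom(200, 1, 0.5))
  f0 <- cox_fit(d0, "x")
  expect_lt(abs(f0$coefficients$estimate), 2.5 * f0$coefficients$std.error)

  # parameter recovery: true HR 2 at n=500 within 2 SE
  set.seed(10)
  xr <- stats::rbinom(500, 1, 0.5)
  dr <- surv_df(stats::rexp(500, 0.05 * 2^xr), rep(1, 500), x = xr)
  fr <- cox_fit(dr, "x")
  expect_lt(abs(fr$coefficients$estimate - log(2)),
            2 * fr$coefficients$std.error)
})

test_that("Cox fit agrees with the survival package under both tie rules", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 80
  d <- surv_df(ceiling(stats::rexp(n, 0.08)),        # heavy ties
               stats::rbinom(n, 1, 0.7),
               x = stats::rnorm(n), z = stats::rbinom(n, 1, 0.4))
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(d, c("x", "z"), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x + z, d,
                           ties = ties)
    expect_equal(mine$coefficients$estimate, unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(mine$coefficients$std.error,
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("complete separation is flagged, not silently reported", {
  d <- surv_df(c(1, 2, 3, 4, 10, 11, 12, 13), rep(1, 8),
               x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_warning(fit <- cox_fit(d, "x"), "separation")
  expect_true(fit$infinite_beta)
  expect_error(cox_fit(surv_df(1:5, rep(1, 5), x = rep(1, 5)), "x"),
               "constant")
})

test_that("univariate scan reduces to cox_fit for one gene and ranks a
          planted gene first", {
  set.seed(12)
  expr <- matrix(stats::rnorm(30), 1, 30, dimnames = list("g1", NULL))
  cl <- surv_df(stats::rexp(30, 0.1) + 0.01, stats::rbinom(30, 1, 0.8))
  scan <- univariate_scan(expr, cl)
  single <- cox_fit(data.frame(x = expr[1, ], time = cl$time,
                               event = cl$event), "x")
  expect_equal(scan$p.value, single$coefficients$p.value)
  expect_equal(scan$hr, single$coefficients$hr)

  # planted gene achieves the smallest p in nearly all replicates
  hits <- 0
  for (s in 1:20) {
    co <- generate_cohort(separable_spec(700 + s, n = 200,
                                         rate_below = 0.1,
                                         rate_above = 0.02))
    ds <- as_dataset(co)
    sc <- univariate_scan(ds$expression, ds$clinical, time = "os_time",
                          event = "os_event")
    hits <- hits + (which.min(sc$p.value) == 1)
  }
  expect_gte(hits, 18)
})

test_that("exact 2xK test reproduces probability-ordering p-values", {
  expect_equal(fisher_exact_2xk(matrix(c(11, 2, 5, 11), 2, byrow = TRUE)),
               0.0079, tolerance = 1e-4 / 0.0079)
  expect_equal(round(fisher_exact_2xk(matrix(c(2, 11, 2, 14), 2,
                                             byrow = TRUE)), 4), 1.0000)
  expect_equal(fisher_exact_2xk(matrix(c(8, 1, 2, 2, 9, 3, 3, 1), 2,
                                       byrow = TRUE)),
               0.8324, tolerance = 1e-4 / 0.8324)

  # cross-check against stats::fisher.test on random 2xK tables
  set.seed(13)
  for (i in 1:40) {
    K <- sample(2:4, 1)
    tab <- matrix(stats::rpois(2 * K, 4), 2)
    tab[1, 1] <- tab[1, 1] + 1   # avoid all-zero rows
    p <- fisher_exact_2xk(tab)
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2xk(matrix(c(0.5, 1, 2, 3), 2)), "integer")
})

test_that("summary-based Welch test matches its scaling identities", {
  eq <- welch_t_summary(5, 1, 10, 5, 1, 10)
  expect_identical(eq$statistic, 0)
  expect_identical(eq$p.value, 1)

  # cohort age comparison from printed summaries
  age <- welch_t_summary(62.6, 2.4, 13, 63, 2.1, 16)
  expect_equal(age$p.value, 0.90, tolerance = 0.01)

  a <- welch_t_summary(3, 0.5, 8, 2, 0.4, 9)
  b <- welch_t_summary(3, 1.0, 8, 2, 0.8, 9)
  expect_equal(b$statistic, a$statistic / 2)
  expect_error(welch_t_summary(1, 0, 5, 1, 0, 5), "zero variance")

  set.seed(14)
  x <- stats::rnorm(12); y <- stats::rnorm(15, 1)
  expect_equal(welch_t(x, y)$p.value, stats::t.test(x, y)$p.value)
})

test_that("paired t test is symmetric and recovers a planted shift", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(paired_t(x, x), "zero-variance")
  set.seed(15)
  y <- x + 1 + stats::rnorm(5, 0, 0.1)
  expect_equal(paired_t(x, y)$p.value, paired_t(y, x)$p.value)
  # planted shift recovered across replicates
  hits <- 0
  for (i in 1:50) {
    a <- stats::rnorm(20)
    b <- a + 0.8 + stats::rnorm(20, 0, 0.5)
    ci <- stats::t.test(b - a)$conf.int
    hits <- hits + (ci[1] <= 0.8 && 0.8 <= ci[2])
  }
  expect_gte(hits, 40)   # ~95% coverage
})

test_that("Pearson correlation handles exact and generated cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(1, 5)), "zero variance")
  # generator round trip at the paired-tissue default correlation
  co <- generate_cohort(cohort_spec(seed = 16))
  r <- pearson_cor(as.vector(co$tumor_expression),
                   as.vector(co$normal_expression))$r
  expect_equal(r, 0.87, tolerance = 0.05)
})

test_that("two-sample KS test separates unequal p-value distributions", {
  set.seed(17)
  a <- stats::runif(300)
  same <- ks_two_sample(a, a)
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)
  hits <- 0
  for (i in 1:20) {
    hits <- hits + (ks_two_sample(stats::runif(500),
                                  stats::runif(500, 0, 0.5))$p.value < 0.001)
  }
  expect_equal(hits, 20)
  # jointly monotone relabeling leaves D unchanged
  b <- stats::runif(200, 0, 0.5)
  expect_equal(ks_two_sample(a, b)$statistic,
               ks_two_sample(qnorm(a), qnorm(b))$statistic)
})

test_that("log-rank statistic equals the Cox score test on tie-free data", {
  set.seed(18)
  for (i in 1:5) {
    n <- 40
    g <- stats::rbinom(n, 1, 0.5)
    d <- surv_df(stats::rexp(n, 0.05 * exp(0.5 * g)),
                 stats::rbinom(n, 1, 0.8), x = g,
                 group = c("lo", "hi")[g + 1])
    lr <- logrank_test(d)
    cx <- cox_fit(d, "x")
    expect_equal(lr$statistic, cx$score_statistic, tolerance = 1e-6)
  }
})
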