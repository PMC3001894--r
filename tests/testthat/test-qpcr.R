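test_that("efficiency and well quantity follow the standard-curve formulas", {
  expect_equal(pcr_efficiency(-3.3219), 2, tolerance = 1e-4)
  expect_equal(pcr_efficiency(-3.5), 10^(1 / 3.5), tolerance = 1e-12)
  # flat-curve limit: very steep slope drives efficiency to 1
  expect_equal(suppressWarnings(pcr_efficiency(-1e9)), 1, tolerance = 1e-6)
  expect_error(pcr_efficiency(3.3), "negative")
  expect_error(pcr_efficiency(0), "negative")

  expect_identical(well_quantity(2, 0), 1)
  expect_identical(well_quantity(2, 1), 0.5)
  expect_equal(well_quantity(1.9307, 20), 1.9307^-20)
  ct <- seq(10, 35, by = 5)
  expect_true(all(diff(well_quantity(1.93, ct)) < 0))
})

test_that("standard-curve fit recovers a known dilution series by OLS", {
  q <- c(0, 0.008, 0.04, 0.2, 1, 5, 25)      # includes a no-template control
  ct <- 20 - 3.4 * log10(q)                   # q = 0 -> infinite, dropped
  curve <- suppressWarnings(fit_standard_curve(q, ct))  # zero-residual lm
  expect_equal(curve$slope, -3.4, tolerance = 1e-10)
  expect_equal(curve$efficiency, 10^(1 / 3.4), tolerance = 1e-10)
  expect_identical(curve$n_points, 6L)        # zero-quantity point dropped
  expect_error(fit_standard_curve(c(0, 1), c(NA, 20)), "two finite")
})

test_that("CV gate removes at most one replicate and only when warranted", {
  clean <- filter_outlier(c(1.0, 1.01, 0.99))
  expect_false(clean$outlier_removed)
  expect_equal(clean$cv, 0.0082, tolerance = 1e-2)

  hit <- filter_outlier(c(1.0, 1.0, 2.0))
  expect_true(hit$outlier_removed)
  expect_identical(hit$removed_index, 3L)
  expect_identical(hit$cv, 0)
  expect_false(hit$qc_warning)

  same <- filter_outlier(c(1, 1, 1))
  expect_false(same$outlier_removed)
  expect_identical(same$cv, 0)

  # pairs cannot lose a point; they are flagged instead
  pair <- filter_outlier(c(1, 3))
  expect_false(pair$outlier_removed)
  expect_true(pair$qc_warning)
  expect_error(filter_outlier(1), "2 or 3")

  # property: never >1 removal, output CV never exceeds input CV
  set.seed(41)
  for (i in 1:200) {
    x <- stats::rlnorm(3, 0, 0.4)
    res <- filter_outlier(x)
    expect_gte(length(res$values), 2L)
    expect_lte(res$cv, cv_in <- stats::sd(x) / mean(x) + 1e-12)
  }
})

test_that("reference normalisation propagates replicate error", {
  nr <- list(avg = 10, cv = 0.08)
  ref <- list(avg = 100, cv = 0.06)
  out <- normalize_expression(nr, ref)
  expect_identical(out$value, 0.1)
  expect_equal(out$stdev, 0.1 * sqrt(0.06^2 + 0.08^2))
  expect_equal(out$log2_value, log2(0.1))

  noiseless <- normalize_expression(list(avg = 5, cv = 0),
                                    list(avg = 50, cv = 0))
  expect_identical(noiseless$stdev, 0)
  expect_error(normalize_expression(nr, list(avg = 0, cv = 0)), "positive")

  # joint rescaling of target and reference leaves the ratio unchanged
  k <- 7.3
  scaled <- normalize_expression(list(avg = 10 * k, cv = 0.08),
                                 list(avg = 100 * k, cv = 0.06))
  expect_identical(scaled$value, out$value)
})

test_that("below-detection is a strict mean-Ct rule", {
  expect_true(below_detection(c(35, 36, 35)))
  expect_false(below_detection(c(20, 20, 20)))
  expect_false(below_detection(c(34, 34, 34)))   # strict inequality
})

test_that("CV bound for resolving a fold change matches its t-test root", {
  cv <- max_cv_for_fold_detection(2, 0.99, 3)
  # independent oracle: numerically solve t_stat(c) = t_crit
  t_stat <- function(c, fold = 2, n = 3) {
    sp2 <- (c^2 + (fold * c)^2) / 2
    (fold - 1) / sqrt(sp2 * 2 / n)
  }
  oracle <- stats::uniroot(function(c) t_stat(c) - stats::qt(0.995, 4),
                           c(1e-4, 2), tol = 1e-12)$root
  expect_equal(cv, oracle, tolerance = 1e-9)
  expect_equal(round(cv, 2), 0.17)

  # monotone increasing in replicate number
  cvs <- vapply(2:8, function(n) max_cv_for_fold_detection(2, 0.99, n),
                numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_error(max_cv_for_fold_detection(1), "exceed 1")
})

test_that("plate processing reproduces a hand-computed matrix", {
  e <- 2                           # slope -1/log10(2)
  slope <- -1 / log10(2)
  wells <- expand.grid(sample_id = c("sA", "sB"),
                       gene_id = c("18S", "nr1", "nr2"),
                       well = 1:3, stringsAsFactors = FALSE)
  ct_map <- c("sA.18S" = 10, "sB.18S" = 11,
              "sA.nr1" = 20, "sB.nr1" = 19,
              "sA.nr2" = 25, "sB.nr2" = 26)
  wells$ct <- ct_map[paste(wells$sample_id, wells$gene_id, sep = ".")]
  curves <- data.frame(gene_id = c("18S", "nr1", "nr2"),
                       slope = rep(slope, 3))
  plate <- process_plate(wells, curves, reference_gene = "18S")
  # hand computation: value = 2^-(ct_gene) / 2^-(ct_ref) = 2^(ct_ref - ct_gene)
  expect_equal(plate$expression["nr1", "sA"], 10 - 20)
  expect_equal(plate$expression["nr1", "sB"], 11 - 19)
  expect_equal(plate$expression["nr2", "sA"], 10 - 25)
  expect_equal(plate$expression["nr2", "sB"], 11 - 26)
  expect_false(plate$all_masked)
  expect_false(any(plate$mask))

  # well order never matters
  perm <- wells[sample(nrow(wells)), ]
  expect_identical(process_plate(perm, curves, "18S")$expression,
                   plate$expression)

  # all target wells below detection -> fully masked matrix for refusal
  dark <- wells
  dark$ct[dark$gene_id != "18S"] <- 36
  darkp <- process_plate(dark, curves, "18S")
  expect_true(darkp$all_masked)
  expect_true(all(darkp$mask))
  # a dark reference is a per-sample error, not a masked cell
  ref_dark <- wells
  ref_dark$ct[ref_dark$gene_id == "18S" & ref_dark$sample_id == "sA"] <- 36
  expect_error(process_plate(ref_dark, curves, "18S"), "below detection")

  # below-detection target gets the per-gene half-minimum floor
  part <- wells
  part$ct[part$sample_id == "sB" & part$gene_id == "nr2"] <- 35
  pp <- process_plate(part, curves, "18S")
  expect_true(pp$mask["nr2", "sB"])
  expect_equal(pp$expression["nr2", "sB"],
               log2(2^pp$expression["nr2", "sA"] / 2))
  expect_error(process_plate(wells[wells$gene_id != "18S", ], curves, "18S"),
               "reference")
})
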