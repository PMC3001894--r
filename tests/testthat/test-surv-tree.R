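test_that("exponential rescaling normalises the cohort event rate to 1", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    tt <- stats::rexp(n, 0.1) + 0.01
    ev <- stats::rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    rt <- exp_rescale(tt, ev)
    expect_equal(sum(ev) / sum(rt), 1, tolerance = 1e-9)
    # the transform is monotone: subject order by time is preserved
    expect_true(all(diff(rt[order(tt)]) >= 0))
  }
  # an event-free subject censored after the first event keeps positive time
  rt <- exp_rescale(c(1, 5, 10), c(1, 0, 1))
  expect_gt(rt[2], 0)
  expect_identical(c(1, 0, 1)[2], 0)
  expect_error(exp_rescale(c(1, 2), c(0, 0)), "no events")
})

test_that("split deviance matches a hand-computed toy and is nonnegative", {
  # identical rates on both sides: no reduction
  d <- c(1, 0, 1, 0); t <- c(1, 1, 1, 1)
  expect_equal(split_deviance(d, t, c(TRUE, TRUE, FALSE, FALSE)), 0,
               tolerance = 1e-12)

  # all events left, none right, hand computation:
  # parent: D=2,T=4,lam=.5; dev = 2*(-2*log(.5) - 0) = 4*log(2)
  # left (events, t=1 each): D=2,T=2,lam=1, dev = 0
  # right (censored): dev = 0 -> reduction = 4*log(2)
  expect_equal(split_deviance(c(1, 1, 0, 0), c(1, 1, 1, 1),
                              c(TRUE, TRUE, FALSE, FALSE)), 4 * log(2))

  set.seed(22)
  for (i in 1:100) {
    n <- 8
    d <- stats::rbinom(n, 1, 0.5)
    t <- stats::rexp(n) + 0.05
    left <- seq_len(n) %in% sample(n, sample(1:(n - 1), 1))
    expect_gte(split_deviance(d, t, left), -1e-10)
  }
  expect_error(split_deviance(d, t, rep(TRUE, 8)), "nonempty")
})

test_that("grown root and child splits equal exhaustive enumeration", {
  set.seed(23)
  cfg <- tree_config(minsplit = 4, minbucket = 2, cp = 0.005)
  for (i in 1:20) {
    n <- sample(8:12, 1)
    expr <- matrix(stats::rnorm(5 * n), 5, n,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    tt <- stats::rexp(n, 0.2) + 0.01
    ev <- stats::rbinom(n, 1, 0.8)
    if (sum(ev) < 2) ev[1:2] <- 1
    tree <- grow(expr, tt, ev, cfg)
    root <- tree$nodes[[tree$root]]
    if (root$is_leaf) next
    rt <- exp_rescale(tt, ev)
    oracle <- best_split_oracle(expr, ev, rt, 2)
    expect_identical(root$gene, paste0("g", oracle$gene))
    expect_equal(root$threshold, oracle$threshold)
    # children: oracle re-run on each side
    for (side in c("left", "right")) {
      child <- tree$nodes[[root[[side]]]]
      if (child$is_leaf) next
      idx <- child$subjects
      sub_oracle <- best_split_oracle(expr[, idx, drop = FALSE],
                                      ev[idx], rt[idx], 2)
      expect_identical(child$gene, paste0("g", sub_oracle$gene))
      expect_equal(child$threshold, sub_oracle$threshold)
    }
  }
})

test_that("degenerate inputs give leaf-only trees", {
  n <- 24
  expr <- matrix(5, 3, n, dimnames = list(paste0("g", 1:3), NULL))
  tt <- stats::rexp(n, 0.1) + 0.01
  tree <- grow(expr, tt, rep(1, n))
  expect_true(tree$nodes[[tree$root]]$is_leaf)

  # identical survival for everyone: no split clears the cp bar
  expr2 <- matrix(stats::rnorm(3 * n), 3, n)
  same <- grow(expr2, rep(5, n), rep(1, n))
  expect_true(same$nodes[[same$root]]$is_leaf)
})

test_that("a planted gene with a clean gap is found at the root, inside
          the gap", {
  hits <- 0
  for (s in 1:10) {
    co <- generate_cohort(separable_spec(900 + s))
    ds <- as_dataset(co)
    tree <- grow(ds$expression, ds$time, ds$event)
    root <- tree$nodes[[tree$root]]
    if (!root$is_leaf && root$gene == "g001" &&
        root$threshold > -10.5 && root$threshold < -6.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("refitting with permuted sample order yields the identical tree", {
  co <- generate_cohort(separable_spec(31))
  ds <- as_dataset(co)
  t1 <- grow(ds$expression, ds$time, ds$event)
  set.seed(32)
  perm <- sample(ncol(ds$expression))
  t2 <- grow(ds$expression[, perm], ds$time[perm], ds$event[perm])
  strip <- function(tr) lapply(tr$nodes, function(nd) {
    nd[c("n", "events", "rate", "is_leaf", "gene", "threshold")]
  })
  expect_equal(strip(t1), strip(t2), tolerance = 1e-12)
})

test_that("tree deviance never increases along the grown sequence", {
  co <- generate_cohort(separable_spec(33))
  ds <- as_dataset(co)
  tree <- grow(ds$expression, ds$time, ds$event,
               tree_config(minsplit = 8, minbucket = 3, cp = 0.001))
  for (nd in tree$nodes) {
    if (nd$is_leaf) next
    expect_lte(tree$nodes[[nd$left]]$deviance +
                 tree$nodes[[nd$right]]$deviance,
               nd$deviance + 1e-9)
  }
})

test_that("cross-validated pruning controls overfitting and keeps real
          structure", {
  # null cohorts prune back to a root leaf in the large majority of runs
  root_only <- 0
  for (s in 1:60) {
    ds <- as_dataset(generate_cohort(null_spec(s)))
    pt <- select_cp(grow(ds$expression, ds$time, ds$event),
                    tree_config(seed = s))
    root_only <- root_only + (length(tree_genes(pt)) == 0)
  }
  expect_gte(root_only / 60, 0.85)

  # a strong planted gene survives pruning as exactly the root split
  kept <- 0
  for (s in 1:30) {
    ds <- as_dataset(generate_cohort(separable_spec(1100 + s)))
    pt <- select_cp(grow(ds$expression, ds$time, ds$event),
                    tree_config(seed = s))
    g <- tree_genes(pt)
    kept <- kept + (length(g) == 1 && g == "g001")
  }
  expect_gte(kept / 30, 0.9)

  # a near-1 complexity threshold leaves only the root
  ds <- as_dataset(generate_cohort(separable_spec(35)))
  big <- grow(ds$expression, ds$time, ds$event, tree_config(cp = 0.99))
  expect_true(big$nodes[[big$root]]$is_leaf)
})

test_that("risk prediction routes by threshold and uses the cohort-rate
          boundary", {
  ds <- as_dataset(generate_cohort(separable_spec(36)))
  pt <- select_cp(grow(ds$expression, ds$time, ds$event),
                  tree_config(seed = 1))
  pred <- predict_risk(pt, ds$expression)
  truth <- generate_cohort(separable_spec(36))$truth
  expect_gte(mean(pred$risk == truth$risk_class), 0.95)
  # high label iff leaf rate above the root rate
  root_rate <- pt$nodes[[pt$root]]$rate
  expect_identical(pred$risk, ifelse(pred$rate > root_rate, "high", "low"))

  # root-leaf tree: everyone low
  leafy <- grow(matrix(1, 2, 20, dimnames = list(c("a", "b"), NULL)),
                stats::rexp(20, 0.1) + 0.01, rep(1, 20))
  all_low <- predict_risk(leafy, matrix(1, 2, 5,
                                        dimnames = list(c("a", "b"), NULL)))
  expect_true(all(all_low$risk == "low"))

  expect_error(predict_risk(pt, ds$expression[-1, ]), "g001")
})

test_that("grown root split agrees with the canonical recursive-partitioning
          implementation", {
  skip_if_not_installed("rpart")
  skip_if_not_installed("survival")
  for (s in 1:5) {
    ds <- as_dataset(generate_cohort(separable_spec(1250 + s)))
    mine <- grow(ds$expression, ds$time, ds$event)
    root <- mine$nodes[[mine$root]]
    df <- data.frame(t(ds$expression))
    df$y <- survival::Surv(ds$time, ds$event)
    ref <- rpart::rpart(y ~ ., data = df, method = "exp",
                        control = rpart::rpart.control(xval = 0))
    expect_identical(root$gene, as.character(ref$frame$var[1]))
    expect_equal(root$threshold, unname(ref$splits[1, "index"]),
                 tolerance = 1e-9)
  }
})
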