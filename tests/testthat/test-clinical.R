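test_that("rank-sum battery matches exact enumeration and tie convention", {
  # exact p for {1,2,3} vs {4,5,6} is 0.1 (2 of 20 assignments as extreme)
  expect_equal(oracle_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  b <- ranksum_battery(data.frame(m = c(1, 2, 3, 4, 5, 6)),
                       rep(1:2, each = 3), alpha = 0.05)
  expect_equal(b$p, 0.1)
  expect_false(b$significant)
  # identical values in both groups -> p = 1
  b2 <- ranksum_battery(data.frame(m = rep(2, 8)), rep(1:2, each = 4))
  expect_equal(b2$p, 1)
  # random exact instances against the enumeration oracle
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(7)
    b3 <- ranksum_battery(data.frame(m = c(x, y)),
                          rep(1:2, c(6, 7)))
    expect_equal(b3$p, oracle_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum battery applies Bonferroni at alpha / n_measures", {
  set.seed(13)
  meas <- matrix(rnorm(60 * 11), 60, 11)
  meas[, 1] <- meas[, 1] + rep(c(0, 3), each = 30)   # one huge shift
  b <- ranksum_battery(meas, rep(1:2, each = 30), alpha = 0.01)
  expect_true(b$significant[1])
  expect_equal(b$significant, b$p < 0.01 / 11)
  expect_equal(b$neg_log10_p, -log10(b$p))
})

test_that("unpenalized Cox beta matches grid-search partial-likelihood oracle", {
  # interleaved failure order so the partial-likelihood maximizer is finite
  # (fully separated groups, as in textbook toys, have an infinite MLE)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  f <- fit_cox(time, event, data.frame(g = x), penalty_strength = 0)
  expect_equal(unname(f$coefficients["g"]),
               oracle_cox_beta(time, event, x), tolerance = 1e-3)
})

test_that("all-zero covariates give zero beta and chance concordance", {
  set.seed(14)
  f <- fit_cox(rexp(20), rbinom(20, 1, 0.8), data.frame(z = rep(0, 20)),
               penalty_strength = 0.1)
  expect_equal(unname(f$coefficients), 0)
  expect_true(is.nan(f$concordance) || abs(f$concordance - 0.5) < 1e-10)
  expect_error(fit_cox(1:4, rep(0, 4), data.frame(z = rnorm(4))), "no events")
})

test_that("concordance matches pair-enumeration oracle and extremes", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 1)
  risk <- c(5, 4, 3, 2, 1)                 # perfect ordering
  expect_equal(concordance_index(risk, time, event), 1)
  expect_equal(concordance_index(-risk, time, event), 0)
  set.seed(15)
  r <- rnorm(5)
  expect_equal(concordance_index(r, time, event),
               oracle_concordance(r, time, event), tolerance = 1e-12)
})

test_that("log-rank test matches hand tabulation and survdiff", {
  time <- c(2, 4, 4, 6, 8, 10, 12, 14)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(1:2, each = 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-10)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$neg_log2_p, -log2(lr$p))
  # label swap invariance
  expect_equal(logrank_test(time, event, 3 - group)$statistic, lr$statistic)
  # identical groups -> statistic 0, p 1
  lr0 <- logrank_test(rep(time, 2), rep(event, 2), rep(1:2, each = 8))
  expect_equal(lr0$statistic, 0, tolerance = 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-10)
})

test_that("conversion curves start at 1, decrease, and collapse at beta = 0", {
  set.seed(16)
  n <- 40
  f <- fit_cox(rexp(n), rbinom(n, 1, 0.7),
               data.frame(a = rnorm(n), b = rnorm(n)), penalty_strength = 0)
  cc <- conversion_curves(f, rbind(g1 = c(a = 1, b = 0), g2 = c(a = -1, b = 0)))
  for (g in unique(cc$group)) {
    s <- cc$survival[cc$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
  f0 <- fit_cox(rexp(n), rep(1, n), data.frame(z = rep(0, n)))
  cc0 <- conversion_curves(f0, rbind(g1 = c(z = 0), g2 = c(z = 5)))
  expect_equal(cc0$survival[cc0$group == "g1"],
               cc0$survival[cc0$group == "g2"])
})

test_that("progression curves average correctly and flag small cells", {
  long <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = 2),
    month = rep(c(0, 12), 3),
    measure = "MMSE",
    value = c(1, 2, 3, 4, 5, 6))
  labels <- c(a = 1, b = 1, c = 2)
  pc <- progression_curves(long, labels)
  m0 <- pc[pc$month == 0 & pc$subtype == 1, ]
  expect_equal(m0$mean, 2)                 # mean of 1, 3
  expect_equal(m0$n, 2L)
  s2 <- pc[pc$subtype == 2, ]
  expect_false(any(s2$reliable))
  expect_equal(s2$lower, s2$mean)
  # constant single-subtype values: flat line, zero-width CI
  long2 <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                      month = rep(c(0, 6, 12), 2), measure = "X", value = 7)
  pc2 <- progression_curves(long2, c(a = 1, b = 1))
  expect_equal(pc2$mean, rep(7, 3))
  expect_equal(pc2$upper - pc2$lower, rep(0, 3))
})

test_that("progression CI width shrinks as 1/sqrt(n)", {
  set.seed(17)
  widths <- sapply(c(10, 40, 160), function(n) {
    long <- data.frame(sample_id = sprintf("s%03d", 1:n), month = 0,
                       measure = "X", value = rnorm(n))
    labels <- stats::setNames(rep(1, n), long$sample_id)
    pc <- progression_curves(long, labels)
    pc$upper - pc$lower
  })
  expect_equal(widths[2] / widths[1], 0.5, tolerance = 0.35)
  expect_equal(widths[3] / widths[2], 0.5, tolerance = 0.35)
})

test_that("penalized Cox recovers a known hazard ratio", {
  set.seed(18)
  betas <- replicate(10, {
    g <- rep(0:1, each = 250)
    tt <- rexp(500, rate = 0.02 * 2^g)
    cens <- rexp(500, rate = 0.005)
    f <- fit_cox(pmin(tt, cens), as.integer(tt <= cens),
                 data.frame(g = g), penalty_strength = 0.01)
    f$coefficients["g"]
  })
  expect_lt(abs(mean(betas) - log(2)), 0.2)
})
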