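test_that("Mann-Whitney exact path matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
  # identical samples: p = 1 by symmetry
  expect_equal(mann_whitney_u(c(2, 5, 9), c(2.1, 5.1, 9.1) - 0.1)$p_value, 1)
  # enumeration oracle over random small samples of several sizes
  set.seed(77)
  for (n in c(3, 5, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_enum_oracle(x, y))
  }
  # invariance under monotone transform of the pooled data
  set.seed(78)
  x <- rnorm(8); y <- rnorm(8) + 1
  expect_equal(mann_whitney_u(exp(x), exp(y))$p_value,
               mann_whitney_u(x, y)$p_value)
  # tied data fall back to the corrected normal approximation
  r2 <- mann_whitney_u(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_false(r2$exact)
  expect_error(mann_whitney_u(numeric(0), 1), class = "koaev_empty_input")
})

test_that("Kruskal-Wallis H matches the rank-sum formula", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r$statistic), 32 / 7, tolerance = 1e-12)
  # three identical groups: H = 0 is the degenerate floor
  rid <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(rid$statistic), 0)
  expect_equal(rid$p_value, 1)
  # brute-force rank computation oracle on tie-free data
  set.seed(12)
  g <- list(rnorm(5), rnorm(4), rnorm(6))
  pooled <- unlist(g)
  rk <- rank(pooled)
  sizes <- lengths(g)
  idx <- split(seq_along(pooled), rep(seq_along(g), sizes))
  n <- length(pooled)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(g), function(i) {
      sizes[i] * (mean(rk[idx[[i]]]) - (n + 1) / 2)^2
    }, numeric(1)))
  expect_equal(unname(kruskal_wallis(g)$statistic), h, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, 4:6)), class = "koaev_bad_input")
})

test_that("Fisher exact two-sided p follows the probability-mass rule", {
  # the study's sex table: KOA 2M/6F vs control 5M/3F
  r <- fisher_exact_2x2(matrix(c(2, 6, 5, 3), 2, 2, byrow = TRUE))
  expect_equal(r$p_value, 4050 / 12870, tolerance = 1e-10)
  expect_equal(round(r$p_value, 3), 0.315)
  # proportional rows give p = 1
  expect_equal(fisher_exact_2x2(matrix(c(3, 5, 3, 5), 2, 2))$p_value, 1)
  # full-enumeration oracle over random small tables
  set.seed(33)
  for (i in 1:20) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2, 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-9)
    expect_lte(p, 1)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2, 2)),
               class = "koaev_bad_input")
})

test_that("covariate-adjusted linear model recovers planted group effects", {
  set.seed(55)
  n <- 200
  grp <- rep(c("control", "KOA"), each = n / 2)  # control is the reference
  covs <- data.frame(age = rnorm(n, 50, 8), bmi = rnorm(n, 27, 3))
  y <- 2.0 * (grp == "KOA") + 0.01 * covs$age + rnorm(n)
  r <- covariate_adjusted_test(y, grp, covs)
  expect_lt(abs(r$coefficient - 2.0), 0.2)
  expect_lt(r$p_value, 0.01)
  # null calibration: p-values uniform under no group effect
  set.seed(56)
  ps <- replicate(200, {
    y0 <- rnorm(40)
    g0 <- factor(rep(c("a", "b"), 20))
    c0 <- data.frame(z = rnorm(40))
    covariate_adjusted_test(y0, g0, c0)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # duplicated covariate: rank-deficiency error naming the column
  covs2 <- covs; covs2$age2 <- covs$age
  expect_error(covariate_adjusted_test(y, grp, covs2),
               class = "koaev_rank_deficient")
  # interactions reported on request
  ri <- covariate_adjusted_test(y, grp, covs, interactions = TRUE)
  expect_length(ri$interaction_p, 2)
  expect_true(all(ri$interaction_p >= 0 & ri$interaction_p <= 1))
})

test_that("Pearson correlation matches the covariance formula and flags errors", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(unname(pearson_correlation(x, 2 * x + 1)$statistic), 1)
  expect_equal(unname(pearson_correlation(x, -x)$statistic), -1)
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  r <- pearson_correlation(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r$statistic), r_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, stats::cor.test(a, b)$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "koaev_constant_variable")
})

test_that("Benjamini-Hochberg step-up reproduces hand-checked thresholds", {
  rep1 <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.2), alpha = 0.05)
  expect_identical(rep1$k_star, 4L)
  expect_equal(rep1$critical_value, 0.04)
  expect_identical(sum(rep1$reject), 4L)
  expect_true(all(diff(rep1$thresholds) > 0))
  # all p = 1: nothing rejected, flag says the threshold was unmet
  rep0 <- benjamini_hochberg(rep(1, 6), alpha = 0.05)
  expect_identical(sum(rep0$reject), 0L)
  expect_false(rep0$threshold_met)
  # the study's critical value: alpha = 0.05, k* = 5 of m = 38
  p38 <- c(seq(0.0001, 0.0061, length.out = 5), seq(0.2, 0.9, length.out = 33))
  rep38 <- benjamini_hochberg(p38, alpha = 0.05)
  expect_identical(rep38$k_star, 5L)
  expect_equal(round(rep38$critical_value, 5), 0.00658)
  # agreement with the standard step-up adjustment
  set.seed(9)
  p <- runif(40)^2
  repx <- benjamini_hochberg(p, alpha = 0.05)
  expect_identical(unname(repx$reject), p.adjust(p, "BH") <= 0.05)
})

test_that("BH rejections grow with alpha and dominate Bonferroni", {
  set.seed(10)
  p <- runif(30)^3
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  nrej <- vapply(alphas, function(a) sum(benjamini_hochberg(p, a)$reject),
                 integer(1))
  expect_true(all(diff(nrej) >= 0))
  for (a in alphas) {
    bh <- benjamini_hochberg(p, a)$reject
    bonf <- p <= a / length(p)
    expect_true(all(bh[bonf]))  # Bonferroni rejections are a subset
  }
})

test_that("batch cohort statistics emit the per-variable contract", {
  g <- strong_cohort(3)
  st <- cohort_group_stats(g$table)
  expect_identical(names(st),
                   c("variable", "method", "statistic", "p", "exact",
                     "bh_reject"))
  expect_identical(nrow(st), ncol(g$table$values))
  expect_true(all(st$p >= 0 & st$p <= 1))
  # planted effects are detected, residual noise mostly is not
  grp <- g$truth$group[match(st$variable, g$truth$variable)]
  expect_gt(mean(st$bh_reject[grp != "residual"]), 0.8)
  expect_lt(mean(st$bh_reject[grp == "residual"]), 0.3)
})
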