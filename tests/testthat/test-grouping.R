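test_that("correlation matrix agrees with the per-pair test oracle", {
  g <- strong_cohort(2)
  z <- z_score(g$table)
  cm <- correlation_matrix(z)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 38))
  set.seed(1)
  for (i in 1:10) {
    ab <- sample(38, 2)
    o <- pearson_correlation(z$values[, ab[1]], z$values[, ab[2]])
    expect_equal(cm$r[ab[1], ab[2]], unname(o$statistic), tolerance = 1e-12)
    expect_equal(cm$p[ab[1], ab[2]], o$p_value, tolerance = 1e-12)
  }
  # duplicated variable: off-diagonal r = 1
  dup <- tiny_cohort()
  dup$values[, 2] <- dup$values[, 1]
  cmd <- correlation_matrix(dup)
  expect_equal(cmd$r[1, 2], 1)
  # a pair with <3 complete observations is refused, naming the pair
  sparse <- tiny_cohort()
  sparse$values[1:4, 1] <- NA
  err <- tryCatch(correlation_matrix(sparse), error = identity)
  expect_s3_class(err, "koaev_too_few_values")
  expect_match(conditionMessage(err), "thick_med")
})

test_that("independent variables stay uncorrelated at large n", {
  set.seed(14)
  vals <- matrix(rnorm(2000 * 6), 2000, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
  tab <- cohort_table(vals, rep(c("control", "KOA"), each = 1000),
                      rep(c("M", "F"), 1000))
  cm <- correlation_matrix(tab)
  expect_lt(max(abs(cm$r[upper.tri(cm$r)])), 0.1)
})

test_that("perfectly separated blocks are recovered exactly", {
  # two noiseless blocks: every variable a scalar multiple of its factor
  set.seed(6)
  f1 <- rnorm(12); f2 <- rnorm(12)
  vals <- cbind(f1, 2 * f1, 0.5 * f1, f2, 3 * f2, 0.25 * f2)
  colnames(vals) <- paste0("v", 1:6)
  tab <- cohort_table(vals, rep(c("control", "KOA"), each = 6),
                      rep(c("M", "F"), 6))
  ga <- cluster_variables(correlation_matrix(tab), k = 2)
  expect_equal(adjusted_rand_index(ga$group, rep(c("A", "B"), each = 3)), 1)
  expect_false(any(ga$group == "residual"))
})

test_that("an identity-like correlation structure yields only residuals", {
  set.seed(15)
  vals <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("v", 1:8)))
  tab <- cohort_table(vals, rep(c("control", "KOA"), each = 20),
                      rep(c("M", "F"), 20))
  ga <- cluster_variables(correlation_matrix(tab), k = 3)
  expect_true(all(ga$group == "residual"))
})

test_that("assignment is invariant to variable order up to relabeling", {
  g <- strong_cohort(4)
  z <- z_score(g$table)
  ga1 <- cluster_variables(correlation_matrix(z))
  set.seed(2)
  perm <- sample(ncol(z$values))
  zp <- z
  zp$values <- z$values[, perm]
  zp$descriptors <- z$descriptors[perm, ]
  zp$norm <- lapply(z$norm, function(p) p[perm])
  ga2 <- cluster_variables(correlation_matrix(zp))
  m1 <- setNames(ga1$group, ga1$variable)
  m2 <- setNames(ga2$group, ga2$variable)[names(m1)]
  expect_equal(adjusted_rand_index(m1, m2), 1)
})

test_that("residual group size is monotone in the threshold", {
  g <- strong_cohort(5)
  cm <- correlation_matrix(z_score(g$table))
  sizes <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(thr) {
    sum(cluster_variables(cm, residual_threshold = thr)$group == "residual")
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("correlogram export preserves matrix content under reordering", {
  g <- strong_cohort(6)
  z <- z_score(g$table)
  cm <- correlation_matrix(z)
  ga <- cluster_variables(cm)
  path <- withr::local_tempfile(fileext = ".csv")
  files <- group_correlogram_export(cm, ga, path)
  got <- as.matrix(read.csv(files[["matrix"]], row.names = 1,
                            check.names = FALSE))
  expect_setequal(rownames(got), cm$variables)
  # reordering is a permutation: content preserved
  expect_equal(got[cm$variables, cm$variables], cm$r, tolerance = 1e-12)
  stars <- as.matrix(read.csv(files[["stars"]], row.names = 1,
                              check.names = FALSE))
  expect_identical(unname(stars[rownames(got)[2], rownames(got)[3]]),
                   cm$p[rownames(got)[2], rownames(got)[3]] < 0.05)
  # category ordering requires descriptors and keeps the same content
  files2 <- group_correlogram_export(cm, ga, path, order = "category",
                                     descriptors = z$descriptors)
  got2 <- as.matrix(read.csv(files2[["matrix"]], row.names = 1,
                             check.names = FALSE))
  expect_equal(got2[cm$variables, cm$variables], cm$r, tolerance = 1e-12)
})
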