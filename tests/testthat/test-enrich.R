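groups_from_truth <- function(truth) truth[, c("variable", "group")]

test_that("enrichment has the pseudo-subject contract and provenance", {
  g <- strong_cohort(11)
  z <- z_score(g$table)
  enr <- enrich_dataset(z, groups_from_truth(g$truth), n_replicates = 50,
                        seed = 5)
  expect_identical(dim(enr$features), c(16L * 50L, 6L))
  expect_identical(length(enr$diagnosis), 800L)
  # labels inherited from the source subject
  expect_identical(as.character(enr$diagnosis),
                   as.character(z$diagnosis[match(enr$provenance$source_subject,
                                                  z$subjects)]))
  # every sampled variable belongs to its column's group, and the
  # pseudo-subject carries exactly that variable's Z-score
  lookup <- setNames(g$truth$group, g$truth$variable)
  for (gn in enr$groups) {
    v <- enr$provenance[[paste0("group_", gn, "_variable")]]
    expect_true(all(lookup[v] == gn))
  }
  i <- 137  # arbitrary pseudo-subject
  v1 <- enr$provenance$group_1_variable[i]
  expect_identical(unname(enr$features[i, "group_1"]),
                   unname(z$values[enr$provenance$source_subject[i], v1]))
  # determinism under seed
  enr2 <- enrich_dataset(z, groups_from_truth(g$truth), n_replicates = 50,
                         seed = 5)
  expect_identical(enr$features, enr2$features)
  expect_identical(enr$provenance, enr2$provenance)
})

test_that("single replicate with singleton groups reproduces the original columns", {
  tab <- tiny_cohort()
  z <- z_score(tab)
  groups <- data.frame(variable = colnames(z$values),
                       group = as.character(1:4))
  enr <- enrich_dataset(z, groups, n_replicates = 1, seed = 1)
  expect_equal(unname(enr$features),
               unname(z$values[, groups$variable]))
  expect_error(enrich_dataset(z, groups, n_replicates = 0),
               class = "koaev_bad_input")
  expect_error(
    enrich_dataset(z_score(tiny_cohort(with_missing = TRUE)), groups),
    class = "koaev_missing_values"
  )
})

test_that("group sampling is uniform over the group's variables", {
  g <- strong_cohort(12)
  z <- z_score(g$table)
  truth5 <- g$truth[g$truth$group %in% c("1", "2"), c("variable", "group")]
  truth5 <- truth5[-1, ]  # group 1 now has 5 variables
  enr <- enrich_dataset(z, truth5, n_replicates = 10000, seed = 3)
  picks <- unique(enr$provenance[, c("replicate", "group_1_variable")])
  freq <- table(picks$group_1_variable) / nrow(picks)
  expect_length(freq, 5)
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("separable feature dominates the impurity importance ranking", {
  set.seed(66)
  n <- 16
  diag_lab <- rep(c("control", "KOA"), each = 8)
  vals <- cbind(
    signal = ifelse(diag_lab == "KOA", 1, -1) + rnorm(n, sd = 0.05),
    matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("noise", 1:4)))
  )
  tab <- cohort_table(vals, diag_lab, rep(c("M", "F"), 8))
  z <- z_score(tab)
  groups <- data.frame(variable = colnames(vals),
                       group = as.character(1:5))
  rep <- run_protocol(z, groups, rf_protocol_config(n_repeats = 5,
                                                    n_replicates = 50,
                                                    seed = 2),
                      "enrich_before_split")
  imp <- feature_importance_summary(rep)
  expect_identical(imp$feature[1], "group_1")
  expect_gt(imp$mean_importance[1], 0.5)
  expect_true(rep$importance_reliable)
})

test_that("protocol reports are deterministic and well-formed", {
  g <- strong_cohort(13)
  z <- z_score(g$table)
  grp <- groups_from_truth(g$truth)
  cfg <- rf_protocol_config(n_repeats = 3, n_replicates = 40, seed = 7)
  r1 <- run_protocol(z, grp, cfg, "enrich_after_split")
  r2 <- run_protocol(z, grp, cfg, "enrich_after_split")
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$importance, r2$importance)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
  # normalized importances sum to 1 per repeat
  expect_equal(unname(rowSums(r1$importance)), rep(1, 3), tolerance = 1e-9)
  # original-features and ev_only protocols run on the raw variable space
  ro <- run_protocol(z, NULL, rf_protocol_config(n_repeats = 2, seed = 1),
                     "original_features")
  expect_identical(ncol(ro$importance), 38L)
  rev_ <- run_protocol(z, NULL, rf_protocol_config(n_repeats = 2, seed = 1),
                       "ev_only")
  ev_vars <- z$descriptors$name[z$descriptors$category == "ev_marker"]
  expect_identical(colnames(rev_$importance), ev_vars)
})

test_that("importance summaries average exactly and ignore report order", {
  g <- strong_cohort(14)
  z <- z_score(g$table)
  grp <- groups_from_truth(g$truth)
  cfg1 <- rf_protocol_config(n_repeats = 2, n_replicates = 30, seed = 1)
  cfg2 <- rf_protocol_config(n_repeats = 2, n_replicates = 30, seed = 9)
  ra <- run_protocol(z, grp, cfg1, "enrich_before_split")
  rb <- run_protocol(z, grp, cfg2, "enrich_before_split")
  s1 <- feature_importance_summary(list(ra, rb))
  s2 <- feature_importance_summary(list(rb, ra))
  expect_identical(s1, s2)
  pooled <- rbind(ra$importance, rb$importance)
  expect_equal(s1$mean_importance,
               unname(colMeans(pooled)[s1$feature]), tolerance = 1e-12)
  # identical importances have zero dispersion
  rc <- ra; rc$importance <- ra$importance[c(1, 1), ]
  expect_equal(feature_importance_summary(rc)$sd_importance,
               rep(0, 6))
})
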