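make_particles <- function(diams, capture = "CD63", extra = NULL) {
  n <- length(diams)
  df <- data.frame(
    sample_id = "s1", capture = capture,
    CD41 = FALSE, CD63 = FALSE, CD81 = FALSE, CD9 = FALSE,
    diameter_nm = diams, stringsAsFactors = FALSE
  )
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  ev_particle_table(df, data.frame(sample_id = "s1", dilution_factor = 10,
                                   analyzed_volume_ml = 0.01))
}

test_that("size gates partition the diameter axis with 200 nm on the sEV side", {
  evt <- make_particles(c(30, 100, 150, 200, 500, 1200))
  sev <- size_gate(evt, "sEV")
  lev <- size_gate(evt, "lEV")
  expect_setequal(sev$particles$diameter_nm, c(100, 150, 200))
  expect_identical(lev$particles$diameter_nm, 500)
  # disjoint gates: no particle in both
  expect_length(intersect(sev$particles$diameter_nm,
                          lev$particles$diameter_nm), 0)
  expect_identical(attr(sev, "gate_log")$kept + attr(sev, "gate_log")$dropped, 6L)
})

test_that("subpopulation profile counts the direct example and conserves totals", {
  # capture CD63, 10 particles: 4 single+, 3 +CD9, 2 +CD81, 1 +CD81+CD9
  evt <- make_particles(rep(100, 10), extra = list(
    CD81 = c(rep(FALSE, 7), TRUE, TRUE, TRUE),
    CD9 = c(rep(FALSE, 4), TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  ))
  prof <- subpopulation_profile(evt, "CD63")
  got <- setNames(prof$percentage, prof$pattern)
  expect_equal(unname(got[c("CD63", "CD63+CD9", "CD63+CD81", "CD63+CD81+CD9")]),
               c(40, 30, 20, 10))
  expect_equal(sum(prof$percentage), 100, tolerance = 1e-9)
  expect_identical(sum(prof$count), attr(prof, "total"))
  # capture self-positivity is enforced at ingest
  expect_true(all(evt$particles$CD63))
})

test_that("profile equals an independent brute-force pattern tally", {
  set.seed(5)
  n <- 500
  df <- data.frame(
    sample_id = "s1", capture = "CD81",
    CD41 = sample(c(TRUE, FALSE), n, TRUE),
    CD63 = sample(c(TRUE, FALSE), n, TRUE),
    CD81 = FALSE,
    CD9 = sample(c(TRUE, FALSE), n, TRUE),
    diameter_nm = runif(n, 60, 190), stringsAsFactors = FALSE
  )
  evt <- ev_particle_table(df, data.frame(sample_id = "s1",
                                          dilution_factor = 50,
                                          analyzed_volume_ml = 0.02))
  prof <- subpopulation_profile(evt, "CD81")
  oracle <- pattern_tally_oracle(evt$particles, "CD81", prof$pattern)
  expect_equal(prof$count, unname(oracle))
  expect_equal(prof$concentration_per_ml, prof$count * 50 / 0.02)
})

test_that("zero captured particles raise a no-data error", {
  evt <- make_particles(c(100, 120), capture = "CD9")
  expect_error(subpopulation_profile(evt, "CD41"), class = "koaev_no_particles")
  expect_error(subpopulation_profile(evt, "CD61-scatter"),
               class = "koaev_bad_capture")
})

test_that("concentration accounting is linear and matches printed scales", {
  expect_equal(concentration_per_ml(100, 10, 0.01), 1e5)
  expect_equal(concentration_per_ml(0, 10, 0.01), 0)
  # 160 events at 50x dilution in 0.01 mL: the large-EV serum scale
  expect_equal(concentration_per_ml(160, 50, 0.01), 8.0e5)
  # linear in count and in dilution
  expect_equal(concentration_per_ml(320, 50, 0.01),
               2 * concentration_per_ml(160, 50, 0.01))
  expect_equal(concentration_per_ml(160, 100, 0.01),
               2 * concentration_per_ml(160, 50, 0.01))
  expect_error(concentration_per_ml(10, 10, 0), class = "koaev_bad_volume")
})

test_that("cohort EV features emit 4 totals + 32 counts + 32 percentages", {
  ps <- koa_scenario_presets()
  subjects <- paste0("S", 1:3)
  evt <- size_gate(generate_ev_particles(ps$strong_structure$ev_sev,
                                         subjects[1:2], seed = 8), "sEV")
  feats <- cohort_ev_features(evt, subjects)
  expect_identical(dim(feats), c(3L, 4L + 32L + 32L))
  expect_identical(rownames(feats), subjects)
  # subject without a run is fully masked missing
  expect_true(all(is.na(feats["S3", ])))
  expect_false(anyNA(feats[c("S1", "S2"), ]))
  # conservation: pattern counts per capture sum to the total captured
  for (m in c("CD41", "CD63", "CD81", "CD9")) {
    cnt_cols <- grep(sprintf("^%s(_CD|_count)", m),
                     colnames(feats), value = TRUE)
    cnt_cols <- setdiff(grep("_count$", cnt_cols, value = TRUE),
                        paste0(m, "_total_count"))
    expect_equal(sum(feats["S1", cnt_cols]),
                 unname(feats["S1", paste0(m, "_total_count")]))
  }
  desc <- attr(feats, "descriptors")
  expect_true(all(desc$category == "ev_marker"))
})
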