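# fixtures built in code, shared across test files

# tiny deterministic cohort: 6 subjects x 4 variables, optional missing cell
tiny_cohort <- function(with_missing = FALSE) {
  set.seed(404)
  vals <- matrix(rnorm(24), 6, 4,
                 dimnames = list(NULL, c("thick_med", "walk_s", "vas_pain", "lici")))
  if (with_missing) vals[2, "lici"] <- NA
  cohort_table(
    vals,
    diagnosis = rep(c("control", "KOA"), each = 3),
    sex = c("M", "F", "M", "F", "F", "M"),
    variable_descriptors(colnames(vals),
                         c("cartilage", "objective_function",
                           "subjective_pain", "objective_pain")),
    subjects = paste0("S", 1:6)
  )
}

# strong-structure synthetic cohort at a fixed seed, plus its truth
strong_cohort <- function(seed = 1) {
  cfg <- koa_scenario_presets()$strong_structure$cohort
  cfg$seed <- seed
  generate_cohort(cfg)
}

# independent enumeration oracle for the exact two-sided Mann-Whitney p:
# walk every labeling of the pooled data, tally the U distribution
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# independent hypergeometric enumeration oracle for two-sided Fisher p
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force pattern tally: for each canonical pattern label, count the
# particles whose positivity over the non-capture markers matches exactly
pattern_tally_oracle <- function(particles, capture, patterns) {
  others <- setdiff(c("CD41", "CD63", "CD81", "CD9"), capture)
  sub <- particles[particles$capture == capture, , drop = FALSE]
  vapply(patterns, function(lab) {
    want <- strsplit(lab, "+", fixed = TRUE)[[1]]
    hit <- rep(TRUE, nrow(sub))
    for (m in others) hit <- hit & (sub[[m]] == (m %in% want))
    sum(hit)
  }, numeric(1))
}
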