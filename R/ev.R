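# Single-EV accounting: particle tables, size gating, co-localization
# (subpopulation) profiles per capture marker, and per-mL concentrations.

#' Tetraspanin panel markers
#'
#' The four surface markers read out per captured particle by the
#' single-particle imaging assay; CD61 large-EV counts come from flow
#' cytometry and carry totals only.
#' @export
ev_panel <- c("CD41", "CD63", "CD81", "CD9")

ev_capture_channels <- c(ev_panel, "CD61-scatter")

#' Construct a per-particle EV detection table
#'
#' One row per detected particle: the capture channel it was bound on, its
#' positivity over the tetraspanin panel, and its diameter. Per-sample
#' metadata (dilution factor, analysed volume) supports concentration
#' accounting. Capture-channel self-positivity is enforced at ingest: a
#' particle captured on a panel marker is positive for that marker by
#' construction.
#'
#' @param particles `data.frame` with columns `sample_id`, `capture`,
#'   `CD41`, `CD63`, `CD81`, `CD9` (0/1 or logical), `diameter_nm`.
#' @param samples `data.frame` with columns `sample_id`, `dilution_factor`
#'   (>= 1), `analyzed_volume_ml` (> 0).
#' @return An object of class `ev_particle_table`.
#' @export
ev_particle_table <- function(particles, samples) {
  need <- c("sample_id", "capture", ev_panel, "diameter_nm")
  if (!all(need %in% names(particles))) {
    stop_koaev(sprintf("particle table missing column(s): %s",
                       paste(setdiff(need, names(particles)), collapse = ", ")),
               "koaev_schema_mismatch")
  }
  particles <- particles[, need, drop = FALSE]
  particles$sample_id <- as.character(particles$sample_id)
  particles$capture <- as.character(particles$capture)
  bad <- setdiff(unique(particles$capture), ev_capture_channels)
  if (length(bad)) {
    stop_koaev(sprintf("unknown capture channel: %s", bad[1]),
               "koaev_bad_capture")
  }
  for (m in ev_panel) particles[[m]] <- as.logical(particles[[m]])
  if (nrow(particles) && any(!is.finite(particles$diameter_nm) |
                             particles$diameter_nm <= 0)) {
    stop_koaev("particle diameters must be positive", "koaev_bad_diameter")
  }
  # self-positivity by construction (SP-IRIS capture semantics)
  for (m in ev_panel) {
    onchan <- particles$capture == m
    particles[[m]][onchan] <- TRUE
  }
  sneed <- c("sample_id", "dilution_factor", "analyzed_volume_ml")
  if (!all(sneed %in% names(samples))) {
    stop_koaev("sample metadata needs sample_id, dilution_factor, analyzed_volume_ml",
               "koaev_schema_mismatch")
  }
  samples <- samples[, sneed, drop = FALSE]
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop_koaev("duplicate sample_id in metadata", "koaev_duplicate_subject")
  }
  if (any(samples$dilution_factor < 1)) {
    stop_koaev("dilution_factor must be >= 1", "koaev_bad_dilution")
  }
  if (any(samples$analyzed_volume_ml <= 0)) {
    stop_koaev("analyzed_volume_ml must be positive", "koaev_bad_volume")
  }
  orphan <- setdiff(unique(particles$sample_id), samples$sample_id)
  if (length(orphan)) {
    stop_koaev(sprintf("particles reference unknown sample(s): %s",
                       paste(orphan, collapse = ", ")),
               "koaev_schema_mismatch")
  }
  structure(list(particles = particles, samples = samples),
            class = "ev_particle_table")
}

#' @export
print.ev_particle_table <- function(x, ...) {
  cat(sprintf("<ev_particle_table> %d particles, %d sample(s)\n",
              nrow(x$particles), nrow(x$samples)))
  invisible(x)
}

#' Read EV particle and sample-metadata CSVs
#'
#' @param particle_path CSV `sample_id,capture,CD41,CD63,CD81,CD9,diameter_nm`
#'   with 0/1 positivity.
#' @param samples_path CSV `sample_id,dilution_factor,analyzed_volume_ml`.
#' @return An [ev_particle_table()].
#' @export
read_ev_particles <- function(particle_path, samples_path) {
  ev_particle_table(
    read.csv(particle_path, stringsAsFactors = FALSE),
    read.csv(samples_path, stringsAsFactors = FALSE)
  )
}

#' Write EV particle and sample-metadata CSVs
#'
#' @param evt an [ev_particle_table()].
#' @param particle_path,samples_path output paths.
#' @return `particle_path`, invisibly.
#' @export
write_ev_particles <- function(evt, particle_path, samples_path) {
  p <- evt$particles
  for (m in ev_panel) p[[m]] <- as.integer(p[[m]])
  write.csv(p, particle_path, row.names = FALSE, quote = FALSE)
  write.csv(evt$samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(particle_path)
}

#' Size-gate an EV particle table
#'
#' Small EVs (`sEV`) keep diameters in the closed interval \[50, 200\] nm;
#' large EVs (`lEV`) keep (200, 1000\] nm. The shared 200 nm endpoint is
#' assigned to the small-EV gate, so the two regimes partition the
#' 50-1000 nm range with no particle in both. Kept/dropped counts are
#' attached as the `"gate_log"` attribute.
#'
#' @param evt an [ev_particle_table()].
#' @param regime `"sEV"` or `"lEV"`.
#' @return A gated [ev_particle_table()] (possibly empty).
#' @export
size_gate <- function(evt, regime = c("sEV", "lEV")) {
  stopifnot(inherits(evt, "ev_particle_table"))
  regime <- match.arg(regime)
  d <- evt$particles$diameter_nm
  keep <- if (regime == "sEV") d >= 50 & d <= 200 else d > 200 & d <= 1000
  out <- evt
  out$particles <- evt$particles[keep, , drop = FALSE]
  rownames(out$particles) <- NULL
  attr(out, "gate_log") <- list(regime = regime, kept = sum(keep),
                                dropped = sum(!keep))
  out
}

# canonical order of the 8 positivity patterns over the three non-capture
# markers: single-positive first, then doubles, triples, quadruple, each in
# panel order
ev_pattern_levels <- function(capture) {
  others <- setdiff(ev_panel, capture)
  subsets <- list(character(0))
  for (k in 1:3) {
    cmb <- utils::combn(others, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  vapply(subsets, function(s) paste(c(capture, s), collapse = "+"),
         character(1))
}

ev_pattern_of <- function(particles, capture) {
  others <- setdiff(ev_panel, capture)
  lab <- rep(capture, nrow(particles))
  pos <- as.matrix(particles[, others, drop = FALSE])
  add <- apply(pos, 1, function(p) paste(others[p], collapse = "+"))
  ifelse(add == "", lab, paste(lab, add, sep = "+"))
}

# reorder a pattern label's non-capture markers into canonical panel order
# (internal; inputs are already canonical when built by ev_pattern_of)

#' Co-localization (subpopulation) profile for one capture marker
#'
#' Tallies the captured particles of one tetraspanin capture channel over the
#' 8 positivity patterns of the other three panel markers (single-positive,
#' each double, each triple, quadruple). Percentages use the captured
#' particles on that channel as denominator and sum to 100; concentrations
#' are `count * dilution_factor / analyzed_volume_ml` when the table holds a
#' single sample (or `sample_id` is given), `NA` otherwise.
#'
#' @param evt an [ev_particle_table()] (typically sEV-gated).
#' @param capture one of `CD41`, `CD63`, `CD81`, `CD9`.
#' @param sample_id optional sample to profile when `evt` holds several.
#' @return A `data.frame` of class `subpopulation_profile` with columns
#'   `pattern`, `count`, `percentage`, `concentration_per_ml`, plus
#'   attributes `capture` and `total`.
#' @export
subpopulation_profile <- function(evt, capture, sample_id = NULL) {
  stopifnot(inherits(evt, "ev_particle_table"))
  if (!capture %in% ev_panel) {
    stop_koaev(
      "pattern profiling applies to the tetraspanin panel; CD61 large-EV counts are totals only",
      "koaev_bad_capture"
    )
  }
  p <- evt$particles
  if (!is.null(sample_id)) p <- p[p$sample_id == sample_id, , drop = FALSE]
  p <- p[p$capture == capture, , drop = FALSE]
  if (!nrow(p)) {
    stop_koaev(
      sprintf("no particles captured on channel %s%s: no data (distinct from an all-negative stain)",
              capture,
              if (is.null(sample_id)) "" else sprintf(" for sample %s", sample_id)),
      "koaev_no_particles"
    )
  }
  lev <- ev_pattern_levels(capture)
  pat <- factor(ev_pattern_of(p, capture), levels = lev)
  counts <- as.integer(table(pat))
  total <- sum(counts)
  sid <- unique(p$sample_id)
  conc <- rep(NA_real_, length(counts))
  if (length(sid) == 1L) {
    meta <- evt$samples[evt$samples$sample_id == sid, ]
    conc <- concentration_per_ml(counts, meta$dilution_factor,
                                 meta$analyzed_volume_ml)
  }
  out <- data.frame(
    pattern = lev,
    count = counts,
    percentage = 100 * counts / total,
    concentration_per_ml = conc,
    stringsAsFactors = FALSE
  )
  attr(out, "capture") <- capture
  attr(out, "total") <- total
  class(out) <- c("subpopulation_profile", "data.frame")
  out
}

#' Particle count to concentration per mL of serum
#'
#' @param count non-negative event count.
#' @param dilution_factor sample pre-dilution (>= 1).
#' @param analyzed_volume_ml analysed volume in mL (> 0).
#' @return `count * dilution_factor / analyzed_volume_ml`, in particles/mL.
#' @export
concentration_per_ml <- function(count, dilution_factor, analyzed_volume_ml) {
  if (any(analyzed_volume_ml <= 0)) {
    stop_koaev("analyzed volume must be positive", "koaev_bad_volume")
  }
  if (any(dilution_factor < 1)) {
    stop_koaev("dilution_factor must be >= 1", "koaev_bad_dilution")
  }
  count * dilution_factor / analyzed_volume_ml
}

#' Subject-level EV feature columns from particle tables
#'
#' Bridges per-particle accounting to the cohort table: for every subject and
#' tetraspanin capture marker, emits the total captured count, the 8
#' co-localization pattern counts, and the 8 pattern percentages, as columns
#' of category `ev_marker`. Subjects without a run on some channel get
#' missing values.
#'
#' @param evt an [ev_particle_table()] whose `sample_id`s are subject ids
#'   (apply [size_gate()] first if the table mixes size regimes).
#' @param subjects character vector of subject ids defining row order.
#' @return A numeric matrix (subjects x features) with a `"descriptors"`
#'   attribute ready to append to a cohort table.
#' @export
cohort_ev_features <- function(evt, subjects) {
  stopifnot(inherits(evt, "ev_particle_table"))
  subjects <- as.character(subjects)
  extra <- setdiff(evt$samples$sample_id, subjects)
  if (length(extra)) {
    warning(sprintf("EV samples with no matching subject: %s",
                    paste(extra, collapse = ", ")))
  }
  cols <- character(0)
  for (m in ev_panel) {
    lev <- ev_pattern_levels(m)
    key <- gsub("\\+", "_", lev)
    cols <- c(cols, paste0(m, "_total_count"),
              paste0(key, "_count"), paste0(key, "_pct"))
  }
  out <- matrix(NA_real_, length(subjects), length(cols),
                dimnames = list(subjects, cols))
  for (s in subjects) {
    has <- evt$particles$sample_id == s
    if (!any(has)) next
    for (m in ev_panel) {
      if (!any(has & evt$particles$capture == m)) next
      prof <- subpopulation_profile(evt, m, sample_id = s)
      key <- gsub("\\+", "_", prof$pattern)
      out[s, paste0(m, "_total_count")] <- attr(prof, "total")
      out[s, paste0(key, "_count")] <- prof$count
      out[s, paste0(key, "_pct")] <- prof$percentage
    }
  }
  attr(out, "descriptors") <- variable_descriptors(
    cols, "ev_marker",
    units = ifelse(grepl("_pct$", cols), "%", "particles")
  )
  out
}

#' Append EV feature columns to a cohort table
#'
#' @param table a [cohort_table()].
#' @param features matrix from [cohort_ev_features()] (same subjects, same
#'   order).
#' @return A [cohort_table()] with the EV columns appended.
#' @export
add_ev_features <- function(table, features) {
  stopifnot(inherits(table, "cohort_table"))
  if (!identical(rownames(features), table$subjects)) {
    stop_koaev("EV feature rows do not match cohort subjects",
               "koaev_schema_mismatch")
  }
  desc <- attr(features, "descriptors")
  cohort_table(cbind(table$values, features), table$diagnosis, table$sex,
               rbind(table$descriptors, desc), subjects = table$subjects)
}
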