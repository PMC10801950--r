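# Per-subject multimodal data model: construction, CSV I/O, standardization,
# complete-case filtering, and small physiology helpers.

#' Variable categories recognised by the cohort data model
#'
#' The seven reporting categories used to organise cohort variables:
#' demographics, cartilage thickness, objective/subjective function,
#' objective pain and sensation, subjective pain/stiffness/mental health,
#' and EV surface-marker variables.
#'
#' @export
variable_categories <- c(
  "demographic", "cartilage", "objective_function", "subjective_function",
  "objective_pain", "subjective_pain", "ev_marker"
)

#' Build a variable descriptor table
#'
#' Descriptors carry per-variable metadata: reporting category, units and
#' whether larger values indicate a worse outcome (used only for reporting
#' direction, never by the statistics).
#'
#' @param name character vector of unique variable names.
#' @param category one of [variable_categories], recycled if length 1.
#' @param units free-text units, recycled.
#' @param higher_is_worse logical, recycled.
#' @return A `data.frame` with columns `name`, `category`, `units`,
#'   `higher_is_worse`.
#' @export
variable_descriptors <- function(name, category, units = "",
                                 higher_is_worse = FALSE) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop_koaev("variable names must be unique", "koaev_duplicate_variable")
  }
  category <- rep_len(as.character(category), length(name))
  bad <- setdiff(unique(category), variable_categories)
  if (length(bad)) {
    stop_koaev(
      sprintf("unknown variable category: %s", paste(bad, collapse = ", ")),
      "koaev_bad_category"
    )
  }
  data.frame(
    name = name,
    category = category,
    units = rep_len(as.character(units), length(name)),
    higher_is_worse = rep_len(as.logical(higher_is_worse), length(name)),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort table
#'
#' The central container of the package: an ordered set of subjects with a
#' diagnosis label (`control`/`KOA`), sex (`M`/`F`), and a numeric
#' subjects-by-variables matrix. Missing measurements are recorded as `NA`
#' (the missingness mask) and are never imputed; analyses declare their own
#' complete-case requirements.
#'
#' @param values numeric matrix, subjects in rows, variables in columns
#'   (column names required; row names taken as subject ids unless `subjects`
#'   is given).
#' @param diagnosis per-subject label, `"control"` or `"KOA"`.
#' @param sex per-subject label, `"M"` or `"F"`.
#' @param descriptors optional descriptor table from [variable_descriptors()];
#'   defaults to category `"demographic"` for every column.
#' @param subjects optional character vector of subject ids.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(values, diagnosis, sex, descriptors = NULL,
                         subjects = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subjects <- as.character(subjects %||% rownames(values) %||%
                             paste0("S", seq_len(nrow(values))))
  if (anyDuplicated(subjects)) {
    stop_koaev("duplicate subject ids", "koaev_duplicate_subject")
  }
  if (is.null(colnames(values))) {
    stop_koaev("variable columns must be named", "koaev_schema_mismatch")
  }
  if (anyDuplicated(colnames(values))) {
    stop_koaev("variable names must be unique", "koaev_duplicate_variable")
  }
  if (length(diagnosis) != nrow(values) || length(sex) != nrow(values) ||
      length(subjects) != nrow(values)) {
    stop_koaev("diagnosis, sex and subjects must match the number of rows",
               "koaev_schema_mismatch")
  }
  bad_dx <- setdiff(unique(as.character(diagnosis)), c("control", "KOA"))
  if (length(bad_dx)) {
    offending <- subjects[as.character(diagnosis) %in% bad_dx]
    stop_koaev(
      sprintf("unknown diagnosis label '%s' (subject %s)",
              bad_dx[1], offending[1]),
      "koaev_bad_diagnosis"
    )
  }
  bad_sex <- setdiff(unique(as.character(sex)), c("M", "F"))
  if (length(bad_sex)) {
    stop_koaev(sprintf("unknown sex label '%s'", bad_sex[1]), "koaev_bad_sex")
  }
  if (is.null(descriptors)) {
    descriptors <- variable_descriptors(colnames(values), "demographic")
  }
  if (!identical(descriptors$name, colnames(values))) {
    stop_koaev("descriptor names must match value columns in order",
               "koaev_schema_mismatch")
  }
  rownames(values) <- subjects
  structure(
    list(
      subjects = subjects,
      diagnosis = factor(as.character(diagnosis), levels = c("control", "KOA")),
      sex = factor(as.character(sex), levels = c("M", "F")),
      values = values,
      descriptors = descriptors
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<%s> %d subjects (%d control, %d KOA), %d variables, %d missing cells\n",
    class(x)[1], length(x$subjects), sum(x$diagnosis == "control"),
    sum(x$diagnosis == "KOA"), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Read a cohort table from tidy CSV
#'
#' Expects one row per subject with columns
#' `subject_id,diagnosis,sex,<var1>,<var2>,...`; empty numeric cells are
#' recorded as missing, never imputed. An optional descriptor sidecar CSV
#' (`name,category,units,higher_is_worse`) supplies variable metadata.
#'
#' @param path path to the cohort CSV.
#' @param descriptors either a descriptor `data.frame` or the path of a
#'   descriptor sidecar CSV; `NULL` for defaults.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, descriptors = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "diagnosis", "sex")
  if (!all(need %in% names(df)[1:3])) {
    stop_koaev("cohort CSV must start with subject_id, diagnosis, sex columns",
               "koaev_schema_mismatch")
  }
  vars <- setdiff(names(df), need)
  if (!length(vars)) {
    stop_koaev("cohort CSV has no variable columns", "koaev_schema_mismatch")
  }
  vals <- as.matrix(df[, vars, drop = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- vars[!vapply(df[vars], is.numeric, logical(1))]
    # allow columns that are all-NA (read as logical)
    coercible <- vapply(df[nonnum], function(x) all(is.na(x)), logical(1))
    if (!all(coercible)) {
      stop_koaev(sprintf("non-numeric variable column: %s",
                         paste(nonnum[!coercible], collapse = ", ")),
                 "koaev_schema_mismatch")
    }
    vals <- matrix(as.numeric(vals), nrow(df), length(vars),
                   dimnames = list(NULL, vars))
  }
  if (is.character(descriptors)) descriptors <- read_descriptors(descriptors)
  if (!is.null(descriptors) && !setequal(descriptors$name, vars)) {
    stop_koaev("descriptor schema does not match cohort columns",
               "koaev_schema_mismatch")
  }
  if (!is.null(descriptors)) {
    descriptors <- descriptors[match(vars, descriptors$name), , drop = FALSE]
    rownames(descriptors) <- NULL
  }
  cohort_table(vals, df$diagnosis, df$sex, descriptors,
               subjects = as.character(df$subject_id))
}

#' Write a cohort table (and optional descriptor sidecar) to CSV
#'
#' Inverse of [read_cohort()]: numeric values are written with 15 significant
#' digits so that a read/write round trip preserves them to that precision.
#'
#' @param table a [cohort_table()].
#' @param path output CSV path.
#' @param descriptor_path optional path for the descriptor sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, descriptor_path = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  num <- as.data.frame(table$values)
  num[] <- lapply(num, function(x) {
    ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE, scientific = FALSE))
  })
  df <- cbind(
    data.frame(subject_id = table$subjects,
               diagnosis = as.character(table$diagnosis),
               sex = as.character(table$sex),
               stringsAsFactors = FALSE),
    num
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(descriptor_path)) {
    write.csv(table$descriptors, descriptor_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

#' Read a descriptor sidecar CSV
#'
#' @param path CSV with columns `name,category,units,higher_is_worse`.
#' @return A descriptor `data.frame` (validated).
#' @export
read_descriptors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  units <- as.character(df$units %||% "")
  units[is.na(units)] <- ""  # empty cells read back as NA
  variable_descriptors(df$name, df$category, units,
                       as.logical(df$higher_is_worse %||% FALSE))
}

#' Convert cohort variables to Z-scores
#'
#' Per-variable standardization across study subjects using the sample
#' standard deviation (n-1 denominator). Missing entries stay missing; the
#' normalization parameters are retained so the transform is auditable.
#'
#' @param table a [cohort_table()]; each variable needs at least 2 non-missing
#'   values and non-zero spread.
#' @return A `zscore_table` (a [cohort_table()] with a `norm` element holding
#'   per-variable `mean` and `sd`).
#' @export
z_score <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  x <- table$values
  nn <- colSums(!is.na(x))
  if (any(nn < 2)) {
    stop_koaev(sprintf("variable with <2 observed values: %s",
                       paste(colnames(x)[nn < 2], collapse = ", ")),
               "koaev_too_few_values")
  }
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  if (any(sdv == 0)) {
    stop_koaev(sprintf("constant variable (sd = 0): %s",
                       paste(colnames(x)[sdv == 0], collapse = ", ")),
               "koaev_constant_variable")
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  out <- table
  out$values <- z
  out$norm <- list(mean = mu, sd = sdv)
  class(out) <- c("zscore_table", "cohort_table")
  out
}

#' Complete-case filtering of a cohort table
#'
#' Mirrors the study's handling of missingness: first drop the listed
#' variables entirely (e.g. those too sparse to analyse), then drop any
#' subject still carrying a missing value. A removal log is attached as the
#' `"removal_log"` attribute.
#'
#' @param table a [cohort_table()].
#' @param drop_variables variable names to remove before subject filtering.
#' @return A filtered [cohort_table()] (retained values untouched).
#' @export
complete_case_filter <- function(table, drop_variables = character()) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(drop_variables, colnames(table$values))
  if (length(unknown)) {
    stop_koaev(sprintf("unknown variable(s): %s",
                       paste(unknown, collapse = ", ")),
               "koaev_schema_mismatch")
  }
  keep_var <- !(colnames(table$values) %in% drop_variables)
  vals <- table$values[, keep_var, drop = FALSE]
  keep_sub <- rowSums(is.na(vals)) == 0
  dropped_subjects <- table$subjects[!keep_sub]
  out <- table
  out$values <- vals[keep_sub, , drop = FALSE]
  out$subjects <- table$subjects[keep_sub]
  out$diagnosis <- table$diagnosis[keep_sub]
  out$sex <- table$sex[keep_sub]
  out$descriptors <- table$descriptors[keep_var, , drop = FALSE]
  rownames(out$descriptors) <- NULL
  if (!is.null(out$norm)) {
    out$norm <- lapply(out$norm, function(p) p[keep_var])
  }
  if (any(table(out$diagnosis) == 0)) {
    stop_koaev("complete-case filter emptied a diagnosis group",
               "koaev_empty_group")
  }
  attr(out, "removal_log") <- list(
    dropped_variables = drop_variables,
    dropped_subjects = dropped_subjects
  )
  out
}

#' Long-interval cortical inhibition (LICI) from paired-pulse MEP amplitudes
#'
#' LICI is reported as the mean of the second (conditioned) motor evoked
#' potential amplitudes divided by the mean of the first (test) amplitudes,
#' expressed as a percentage: `100 * mean(second) / mean(first)`.
#'
#' @param first_meps,second_meps numeric MEP amplitudes (mV) of the first and
#'   second pulse across trials; non-empty, and `mean(first_meps)` must be
#'   positive.
#' @return LICI in percent.
#' @export
lici_percent <- function(first_meps, second_meps) {
  if (!length(first_meps) || !length(second_meps)) {
    stop_koaev("MEP amplitude lists must be non-empty", "koaev_empty_input")
  }
  m1 <- mean(first_meps)
  if (!is.finite(m1) || m1 <= 0) {
    stop_koaev("mean first-pulse MEP amplitude must be positive",
               "koaev_bad_amplitude")
  }
  100 * mean(second_meps) / m1
}

#' Average bilateral (left/right knee) measurements
#'
#' Controls contribute one value per knee variable, computed as the mean of
#' the right and left knee upstream of the cohort table.
#'
#' @param left,right numeric vectors.
#' @return Elementwise `(left + right) / 2`.
#' @export
average_bilateral <- function(left, right) (left + right) / 2
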