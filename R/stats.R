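# Univariate and bivariate group statistics: rank tests, exact contingency
# test, covariate-adjusted linear model, Pearson correlation, and
# Benjamini-Hochberg false-discovery-rate control.

test_result <- function(statistic, p_value, method, n, exact = NA) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n = n, exact = exact),
    class = "koaev_test_result"
  )
}

#' @export
print.koaev_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g%s\n", x$method, x$statistic,
              x$p_value,
              if (isTRUE(x$exact)) " (exact)"
              else if (isFALSE(x$exact)) " (approximate)" else ""))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution (full enumeration over labelings) is used when both samples
#' have at most 10 values and the pooled data are tie-free -- the regime of
#' an 8-vs-8 cohort; otherwise the normal approximation with mid-ranks,
#' tie-corrected variance and continuity correction is used. The `exact`
#' flag records which path ran.
#'
#' @param x,y numeric samples (each non-empty).
#' @return A test result with the U statistic, two-sided p, per-group sizes
#'   and the exactness flag.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop_koaev("both samples must contain at least one value",
               "koaev_empty_input")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  test_result(wt$statistic, wt$p.value, "Mann-Whitney U",
              c(n_x = length(x), n_y = length(y)), exact = use_exact)
}

#' Kruskal-Wallis rank test across three or more groups
#'
#' H statistic with tie correction and a chi-square p-value on k-1 degrees
#' of freedom; used for control vs contralateral vs OA knee comparisons.
#'
#' @param samples list of at least 3 numeric samples, each with >= 2 values.
#' @return A test result.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 3) {
    stop_koaev("Kruskal-Wallis requires at least 3 groups", "koaev_bad_input")
  }
  if (any(vapply(samples, function(s) sum(!is.na(s)), integer(1)) < 2)) {
    stop_koaev("each group needs at least 2 values", "koaev_bad_input")
  }
  kt <- kruskal.test(samples)
  test_result(kt$statistic, kt$p.value, "Kruskal-Wallis",
              vapply(samples, function(s) sum(!is.na(s)), integer(1)),
              exact = FALSE)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities, over tables with the observed margins, of every table no
#' more probable than the one observed (the convention of major statistics
#' packages).
#'
#' @param table 2x2 matrix of non-negative integer counts (e.g. sex by
#'   diagnosis).
#' @return A test result (statistic = odds-ratio estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop_koaev("expected a 2x2 table", "koaev_bad_input")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_koaev("counts must be non-negative integers", "koaev_bad_input")
  }
  ft <- fisher.test(table, alternative = "two.sided")
  test_result(ft$estimate, ft$p.value, "Fisher exact", rowSums(table),
              exact = TRUE)
}

#' Covariate-adjusted group comparison (Gaussian linear model)
#'
#' Group comparison adjusted for confounders: ordinary least squares of
#' `y ~ group + covariates` with an identity link, Wald test on the group
#' coefficient. With `interactions = TRUE` the model adds group x covariate
#' terms and their Wald p-values are reported alongside.
#'
#' @param y numeric outcome.
#' @param group two-level factor (e.g. diagnosis).
#' @param covariates numeric matrix or data.frame of adjustment variables
#'   (e.g. age, BMI); complete cases required.
#' @param interactions also report group x covariate interaction p-values.
#' @return A test result with elements `coefficient` (adjusted group effect)
#'   and, if requested, `interaction_p` added.
#' @export
covariate_adjusted_test <- function(y, group, covariates,
                                    interactions = FALSE) {
  covariates <- as.data.frame(covariates)
  # first observed level is the reference; the reported coefficient is the
  # second level's adjusted shift
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (nlevels(group) != 2) {
    stop_koaev("group must have exactly two levels", "koaev_bad_input")
  }
  df <- data.frame(.y = y, .group = group, covariates, check.names = TRUE)
  if (any(!stats::complete.cases(df))) {
    stop_koaev("complete cases required; filter missing values first",
               "koaev_missing_values")
  }
  X <- model.matrix(~ .group + ., data = df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_koaev(sprintf("rank-deficient design; collinear column(s): %s",
                       paste(dropped, collapse = ", ")),
               "koaev_rank_deficient")
  }
  form <- if (interactions) .y ~ .group * . else .y ~ .group + .
  fit <- lm(form, data = df)
  sm <- summary(fit)$coefficients
  grow <- grep("^\\.group", rownames(sm), value = TRUE)
  main <- grow[!grepl(":", grow)]
  res <- test_result(sm[main, "t value"], sm[main, "Pr(>|t|)"],
                     "covariate-adjusted linear model (Wald)",
                     table(group), exact = FALSE)
  res$coefficient <- sm[main, "Estimate"]
  if (interactions) {
    irows <- grow[grepl(":", grow)]
    res$interaction_p <- setNames(sm[irows, "Pr(>|t|)"],
                                  sub("^\\.group[^:]*:", "group:", irows))
  }
  res
}

#' Pearson correlation with two-sided significance
#'
#' r with the t-based two-sided p-value, `t = r * sqrt((n-2) / (1-r^2))` on
#' n-2 degrees of freedom, over pairwise-complete observations.
#'
#' @param x,y numeric vectors; at least 3 complete pairs and non-zero
#'   variance in each.
#' @return A test result with `r` as the statistic.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop_koaev("at least 3 complete pairs required", "koaev_too_few_values")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_koaev("zero variance in one of the variables",
               "koaev_constant_variable")
  }
  r <- cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  test_result(r, p, "Pearson correlation", n, exact = FALSE)
}

#' Benjamini-Hochberg step-up false-discovery-rate procedure
#'
#' Sorts the m p-values ascending, compares the k-th smallest against the
#' per-rank threshold `alpha * k / m`, and rejects ranks 1..k* where k* is
#' the largest rank whose p-value sits at or below its threshold. The
#' critical value reported is `alpha * k* / m` -- the largest per-rank
#' threshold actually attained. When nothing is rejected the first-rank
#' threshold `alpha / m` is reported with `threshold_met = FALSE`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha target false discovery rate in (0, 1) (default 0.05).
#' @param names optional variable names for reporting.
#' @return An `fdr_report` list: sorted p-values with names, per-rank
#'   thresholds, `k_star`, `critical_value`, `threshold_met`, and `reject`
#'   flags in the original input order.
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05, names = NULL) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_koaev("p-values must lie in [0, 1]", "koaev_bad_input")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_koaev("alpha must lie in (0, 1)", "koaev_bad_input")
  }
  m <- length(p_values)
  names <- names %||% paste0("p", seq_len(m))
  ord <- order(p_values)
  sorted <- p_values[ord]
  thresholds <- alpha * seq_len(m) / m
  hits <- which(sorted <= thresholds)
  k_star <- if (length(hits)) max(hits) else 0L
  reject_sorted <- seq_len(m) <= k_star
  reject <- logical(m)
  reject[ord] <- reject_sorted
  structure(
    list(
      p_sorted = setNames(sorted, names[ord]),
      thresholds = thresholds,
      alpha = alpha,
      m = m,
      k_star = k_star,
      critical_value = if (k_star > 0) alpha * k_star / m else alpha / m,
      threshold_met = k_star > 0,
      reject = setNames(reject, names)
    ),
    class = "fdr_report"
  )
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf(
    "<fdr_report> m = %d, alpha = %g, k* = %d, critical value = %.6g, %d rejection(s)\n",
    x$m, x$alpha, x$k_star, x$critical_value, sum(x$reject)
  ))
  invisible(x)
}

#' Batch per-variable group comparison over a cohort
#'
#' Runs the Mann-Whitney U test (control vs KOA) on every variable with at
#' least 2 observed values per arm, then applies Benjamini-Hochberg control
#' across the family.
#'
#' @param table a [cohort_table()].
#' @param alpha false discovery rate (default 0.05).
#' @return A `data.frame` with columns `variable,method,statistic,p,exact,
#'   bh_reject`, with the [benjamini_hochberg()] report as attribute
#'   `"fdr_report"`.
#' @export
cohort_group_stats <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "cohort_table"))
  ctrl <- table$diagnosis == "control"
  rows <- lapply(colnames(table$values), function(v) {
    x <- table$values[ctrl, v]
    y <- table$values[!ctrl, v]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NULL)
    tr <- mann_whitney_u(x, y)
    data.frame(variable = v, method = tr$method, statistic = tr$statistic,
               p = tr$p_value, exact = tr$exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop_koaev("no variable has >= 2 observed values per diagnosis group",
               "koaev_too_few_values")
  }
  fdr <- benjamini_hochberg(out$p, alpha, names = out$variable)
  out$bh_reject <- unname(fdr$reject[out$variable])
  attr(out, "fdr_report") <- fdr
  out
}
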