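# Correlated variable-group identification: pairwise Pearson correlation
# matrices and hierarchical clustering of variables with a residual group
# for weakly associated variables.

#' Pairwise Pearson correlation matrix of cohort variables
#'
#' Pairwise-complete Pearson correlations between all variables, with the
#' companion matrix of two-sided p-values (t distribution on n-2 df) and the
#' number of complete pairs used per entry.
#'
#' @param table a [cohort_table()] or `zscore_table` (correlations are
#'   scale-invariant, so either works).
#' @return A `correlation_matrix` list with elements `r`, `p`, `n_pairs`,
#'   `variables`.
#' @export
correlation_matrix <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  x <- table$values
  vars <- colnames(x)
  obs <- !is.na(x)
  npair <- crossprod(obs)
  off <- npair[upper.tri(npair)]
  if (any(off < 3)) {
    idx <- which(upper.tri(npair) & npair < 3, arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i) paste(vars[i[1]], vars[i[2]], sep = " / "))
    stop_koaev(sprintf("fewer than 3 complete observations for pair(s): %s",
                       paste(pairs, collapse = "; ")),
               "koaev_too_few_values")
  }
  r <- cor(x, use = "pairwise.complete.obs")
  tstat <- r * sqrt((npair - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = npair - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  structure(
    list(r = r, p = p, n_pairs = npair, variables = vars),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d variables\n", length(x$variables)))
  invisible(x)
}

#' Identify groups of strongly intra-correlated variables
#'
#' Hierarchical agglomerative clustering of variables on the signed
#' correlation distance `d = 1 - r` with Ward linkage, cut into `k` core
#' groups, with a residual group for weakly associated variables. A variable
#' whose mean correlation with the other members of its own cluster falls
#' below `residual_threshold` is reassigned to the residual group (the
#' operationalization of "associates less with the clusters"); singleton
#' clusters go to the residual group outright. Because residual variables
#' distort the initial cut (they occupy cluster slots and can force genuine
#' groups to merge), the cut-and-reassign step is iterated: the surviving
#' core variables are re-clustered at `k` and the residual rule re-applied,
#' until the assignment is stable (at most `max_iter` rounds). Core groups
#' are numbered 1..k' in the variable order of their first member, so the
#' labeling is deterministic given the input.
#'
#' @param corr a [correlation_matrix()].
#' @param k number of core clusters to cut (default 5).
#' @param residual_threshold mean within-group correlation below which a
#'   variable is declared residual (default 0.4).
#' @param method linkage passed to [stats::hclust()]; default `"ward.D"`,
#'   Ward on unsquared distances.
#' @param max_iter maximum refinement rounds (default 5).
#' @return A `group_assignment` data.frame with columns `variable`, `group`
#'   (`"1"`..`"k"` or `"residual"`), `mean_within_r`, and attributes `k`,
#'   `residual_threshold`, `tree` (the full-variable linkage tree).
#' @export
cluster_variables <- function(corr, k = 5, residual_threshold = 0.4,
                              method = "ward.D", max_iter = 5) {
  stopifnot(inherits(corr, "correlation_matrix"))
  vars <- corr$variables
  if (k < 2 || k > length(vars)) {
    stop_koaev("k must lie between 2 and the number of variables",
               "koaev_bad_input")
  }
  if (residual_threshold <= 0 || residual_threshold >= 1) {
    stop_koaev("residual_threshold must lie in (0, 1)", "koaev_bad_input")
  }
  tree <- hclust(as.dist(1 - corr$r), method = method)
  core <- vars
  cut <- NULL
  mean_within <- setNames(rep(NA_real_, length(vars)), vars)
  for (iter in seq_len(max_iter)) {
    if (length(core) <= k) { core <- character(0); break }
    idx <- match(core, vars)
    cut <- cutree(hclust(as.dist(1 - corr$r[idx, idx, drop = FALSE]),
                         method = method), k = k)
    mw <- vapply(seq_along(core), function(i) {
      members <- setdiff(which(cut == cut[i]), i)
      if (!length(members)) return(NA_real_)
      mean(corr$r[idx[i], idx[members]])
    }, numeric(1))
    mean_within[core] <- mw
    keep <- !is.na(mw) & mw >= residual_threshold
    if (all(keep)) break
    core <- core[keep]
    cut <- cut[keep]
  }
  group <- setNames(rep("residual", length(vars)), vars)
  if (length(core)) {
    kept <- unique(cut)  # first-member order within core
    relabel <- setNames(as.character(seq_along(kept)), kept)
    group[core] <- relabel[as.character(cut)]
  }
  out <- data.frame(
    variable = vars,
    group = unname(group),
    mean_within_r = unname(mean_within),
    stringsAsFactors = FALSE
  )
  attr(out, "k") <- length(unique(group[group != "residual"]))
  attr(out, "residual_threshold") <- residual_threshold
  attr(out, "tree") <- tree
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Export an ordered correlogram as CSV
#'
#' Writes the correlation matrix with rows/columns ordered either by
#' identified variable group or by descriptor category, together with a
#' boolean "star" matrix flagging significant correlations (p < 0.05),
#' mirroring the correlogram figures of this analysis style. Reordering is a
#' permutation: matrix content is preserved.
#'
#' @param corr a [correlation_matrix()].
#' @param assignment a [cluster_variables()] result covering all variables.
#' @param path output CSV path for the correlation matrix; the star matrix
#'   goes to the same name with suffix `_stars`.
#' @param order `"group"` (cluster blocks) or `"category"` (descriptor
#'   categories).
#' @param descriptors descriptor table, required for `order = "category"`.
#' @param alpha significance level for stars (default 0.05).
#' @return Named character vector of the two file paths, invisibly.
#' @export
group_correlogram_export <- function(corr, assignment, path,
                                     order = c("group", "category"),
                                     descriptors = NULL, alpha = 0.05) {
  stopifnot(inherits(corr, "correlation_matrix"))
  order <- match.arg(order)
  if (!setequal(assignment$variable, corr$variables)) {
    stop_koaev("assignment must cover every variable in the matrix",
               "koaev_schema_mismatch")
  }
  if (order == "group") {
    key <- assignment$group[match(corr$variables, assignment$variable)]
    key <- factor(key, levels = c(sort(unique(key[key != "residual"])),
                                  "residual"))
  } else {
    if (is.null(descriptors)) {
      stop_koaev("descriptors required for category ordering",
                 "koaev_bad_input")
    }
    key <- factor(descriptors$category[match(corr$variables,
                                             descriptors$name)],
                  levels = variable_categories)
  }
  ord <- order(key, corr$variables)
  r <- corr$r[ord, ord]
  stars <- corr$p[ord, ord] < alpha
  diag(stars) <- FALSE
  star_path <- sub("(\\.csv)?$", "_stars\\1", path)
  if (!grepl("\\.csv$", star_path)) star_path <- paste0(path, "_stars")
  write.csv(r, path)
  write.csv(stars, star_path)
  invisible(c(matrix = path, stars = star_path))
}
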