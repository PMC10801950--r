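# Group-sampling data enrichment and random-forest classification with
# mean-decrease-in-impurity feature importance.
#
# The enrichment exploits strong within-group correlation: each replicate
# samples one variable per variable group (the same choice for every
# subject, so the replicate's features keep their meaning), and every
# original subject contributes one pseudo-subject per replicate carrying the
# sampled variables' Z-scores and the subject's diagnosis label.

#' Group-sampling enrichment of a cohort into pseudo-subjects
#'
#' Builds the enriched dataset: `n_subjects * n_replicates` pseudo-subjects
#' with one feature per variable group (residual group included). For each
#' replicate one variable is drawn uniformly at random from every group;
#' the draw is shared by all subjects within that replicate.
#'
#' @param table a complete-case `zscore_table`.
#' @param groups a [cluster_variables()] assignment (or any data.frame with
#'   `variable` and `group` columns); every group must be non-empty and every
#'   listed variable present in `table`.
#' @param n_replicates number of sampling replicates (default 1000).
#' @param seed RNG seed; identical seeds reproduce the table exactly.
#' @return An `enriched_table` list: `features`
#'   (pseudo-subjects x groups matrix), `diagnosis` (inherited labels),
#'   `provenance` (`source_subject`, `replicate`, and the sampled variable
#'   per group), `groups` (feature/group names).
#' @export
enrich_dataset <- function(table, groups, n_replicates = 1000, seed = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) {
    stop_koaev("enrichment requires a complete-case table",
               "koaev_missing_values")
  }
  if (n_replicates < 1) {
    stop_koaev("n_replicates must be >= 1", "koaev_bad_input")
  }
  vars_by_group <- split(groups$variable, groups$group)
  if (any(!lengths(vars_by_group))) {
    stop_koaev("every group must contain at least one variable",
               "koaev_empty_group")
  }
  missing_vars <- setdiff(unlist(vars_by_group), colnames(table$values))
  if (length(missing_vars)) {
    stop_koaev(sprintf("grouped variable(s) absent from table: %s",
                       paste(missing_vars, collapse = ", ")),
               "koaev_schema_mismatch")
  }
  gnames <- names(vars_by_group)
  num <- suppressWarnings(as.numeric(gnames))
  gnames <- gnames[order(is.na(num), num, gnames)]  # cores 1..k first
  n_sub <- nrow(table$values)
  with_seed_or_not(seed, {
    sampled <- vapply(gnames, function(g) {
      v <- vars_by_group[[g]]
      if (length(v) == 1L) rep(v, n_replicates)
      else sample(v, n_replicates, replace = TRUE)
    }, character(n_replicates))
    sampled <- matrix(sampled, nrow = n_replicates,
                      dimnames = list(NULL, gnames))
    features <- matrix(NA_real_, n_sub * n_replicates, length(gnames),
                       dimnames = list(NULL, paste0("group_", gnames)))
    for (j in seq_along(gnames)) {
      # n_sub x n_replicates block, subjects fastest within replicate
      features[, j] <- as.vector(table$values[, sampled[, j]])
    }
    provenance <- data.frame(
      source_subject = rep(table$subjects, times = n_replicates),
      replicate = rep(seq_len(n_replicates), each = n_sub),
      stringsAsFactors = FALSE
    )
    for (j in seq_along(gnames)) {
      provenance[[paste0("group_", gnames[j], "_variable")]] <-
        rep(sampled[, j], each = n_sub)
    }
    structure(
      list(
        features = features,
        diagnosis = rep(table$diagnosis, times = n_replicates),
        provenance = provenance,
        groups = gnames
      ),
      class = "enriched_table"
    )
  })
}

#' @export
print.enriched_table <- function(x, ...) {
  cat(sprintf("<enriched_table> %d pseudo-subjects x %d group features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Random-forest protocol configuration
#'
#' Ensemble hyperparameters and protocol settings. Defaults follow the
#' classifier specification used throughout: 100 trees, all 6 enriched
#' features candidates at every split (`max_features = 6` -- a genuine
#' restriction on the full-variable protocols), bootstrap resampling,
#' unlimited depth, minimum leaf size 1, an 80/20 train/test split, and 100
#' train/test repeats for averaging. `criterion` records the requested
#' impurity measure; the tree backend (ranger) splits on Gini impurity, so
#' `"entropy"` requests are honoured with Gini and the report records the
#' criterion actually used.
#'
#' @param n_trees trees per forest (default 100).
#' @param criterion `"entropy"` or `"gini"` (see above).
#' @param max_features candidate features per split (default 6).
#' @param bootstrap bootstrap-resample each tree (default TRUE).
#' @param max_depth maximum tree depth, `NULL` = unlimited.
#' @param min_samples_split minimum node size eligible for splitting
#'   (default 2).
#' @param min_samples_leaf minimum terminal-node size (default 1).
#' @param n_repeats train/test repeats averaged into the report
#'   (default 100; 500 is the convention for the original-features
#'   protocol).
#' @param train_fraction fraction of (pseudo-)subjects trained on, in (0,1).
#' @param n_replicates enrichment factor used by the enriching protocols
#'   (default 1000).
#' @param importance_accuracy_gate impurity importances are flagged
#'   unreliable when mean accuracy does not exceed this (default 0.7):
#'   mean-decrease-in-impurity scores are only meaningful when the model
#'   predicts well.
#' @param seed master seed; repeat seeds are derived as seed + repeat index.
#' @return A validated `rf_protocol_config` list.
#' @export
rf_protocol_config <- function(n_trees = 100, criterion = "entropy",
                               max_features = 6, bootstrap = TRUE,
                               max_depth = NULL, min_samples_split = 2,
                               min_samples_leaf = 1, n_repeats = 100,
                               train_fraction = 0.8, n_replicates = 1000,
                               importance_accuracy_gate = 0.7, seed = NULL) {
  if (n_trees < 1) stop_koaev("n_trees must be >= 1", "koaev_bad_config")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_koaev("train_fraction must lie in (0, 1)", "koaev_bad_config")
  }
  if (!criterion %in% c("entropy", "gini")) {
    stop_koaev("criterion must be 'entropy' or 'gini'", "koaev_bad_config")
  }
  structure(
    list(n_trees = as.integer(n_trees), criterion = criterion,
         max_features = as.integer(max_features), bootstrap = bootstrap,
         max_depth = max_depth, min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         n_repeats = as.integer(n_repeats), train_fraction = train_fraction,
         n_replicates = as.integer(n_replicates),
         importance_accuracy_gate = importance_accuracy_gate, seed = seed),
    class = "rf_protocol_config"
  )
}

# stratified index split; guarantees >=1 item per class on each side
stratified_split <- function(labels, fraction) {
  train <- integer(0)
  for (lv in levels(factor(labels))) {
    idx <- which(labels == lv)
    if (length(idx) < 2) {
      stop_koaev(sprintf("class '%s' has fewer than 2 items; cannot split", lv),
                 "koaev_degenerate_split")
    }
    n_tr <- min(max(floor(fraction * length(idx)), 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train),
       test = setdiff(seq_along(labels), train))
}

fit_rf <- function(x, y, config, rseed) {
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = config$n_trees,
    mtry = min(config$max_features, ncol(x)),
    importance = "impurity",
    min.node.size = config$min_samples_leaf,
    max.depth = if (is.null(config$max_depth)) 0 else config$max_depth,
    replace = config$bootstrap,
    splitrule = "gini",
    seed = rseed,
    num.threads = 1
  )
}

subset_subjects <- function(table, idx) {
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$subjects <- table$subjects[idx]
  out$diagnosis <- table$diagnosis[idx]
  out$sex <- table$sex[idx]
  out
}

#' Run a random-forest classification protocol
#'
#' Four protocols over a complete-case Z-score table:
#'
#' * `enrich_before_split` -- enrich the whole cohort, then split the
#'   pseudo-subjects 80/20 at random. Train and test share source subjects,
#'   so near-perfect accuracy is structural (an information-leakage
#'   demonstration of within-group redundancy), not a generalization
#'   estimate.
#' * `enrich_after_split` -- split the original subjects 80/20 first, then
#'   enrich each side with independent replicate samplings; the honest
#'   estimate for new subjects.
#' * `original_features` -- split subjects and train on all original
#'   variables.
#' * `ev_only` -- `original_features` restricted to `ev_marker`-category
#'   columns.
#'
#' Each repeat redraws the split (and, for the enriching protocols, the
#' replicate samplings), trains a forest, and records test accuracy and the
#' normalized training-set mean-decrease-in-impurity feature importances;
#' the report averages over repeats. Splits are stratified by diagnosis so
#' both classes are present on each side; a degenerate split is redrawn a
#' bounded number of times before erroring.
#'
#' @param table a complete-case `zscore_table`.
#' @param groups a [cluster_variables()] assignment (required by the
#'   enriching protocols).
#' @param config an [rf_protocol_config()].
#' @param protocol one of `"enrich_before_split"`, `"enrich_after_split"`,
#'   `"original_features"`, `"ev_only"`.
#' @return An `rf_report` list: `protocol`, `accuracies` (per repeat),
#'   `mean_accuracy`, `importance` (repeats x features), `importance_mean`,
#'   `importance_sd`, `importance_reliable`, `criterion_used`, `config`.
#' @export
run_protocol <- function(table, groups = NULL, config = rf_protocol_config(),
                         protocol = c("enrich_before_split",
                                      "enrich_after_split",
                                      "original_features", "ev_only")) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(config, "rf_protocol_config"))
  protocol <- match.arg(protocol)
  if (anyNA(table$values)) {
    stop_koaev("protocols require a complete-case table",
               "koaev_missing_values")
  }
  if (protocol %in% c("enrich_before_split", "enrich_after_split") &&
      is.null(groups)) {
    stop_koaev("the enriching protocols need a group assignment",
               "koaev_bad_input")
  }
  if (protocol == "ev_only") {
    keep <- table$descriptors$category == "ev_marker"
    if (!any(keep)) {
      stop_koaev("no ev_marker-category variables in the table",
                 "koaev_bad_input")
    }
  }
  one_repeat <- function() {
    for (attempt in 1:10) {
      res <- switch(protocol,
        enrich_before_split = {
          enr <- enrich_dataset(table, groups, config$n_replicates, seed = NULL)
          sp <- stratified_split(enr$diagnosis, config$train_fraction)
          list(xtr = enr$features[sp$train, , drop = FALSE],
               ytr = enr$diagnosis[sp$train],
               xte = enr$features[sp$test, , drop = FALSE],
               yte = enr$diagnosis[sp$test])
        },
        enrich_after_split = {
          sp <- stratified_split(table$diagnosis, config$train_fraction)
          enr_tr <- enrich_dataset(subset_subjects(table, sp$train), groups,
                                   config$n_replicates, seed = NULL)
          enr_te <- enrich_dataset(subset_subjects(table, sp$test), groups,
                                   config$n_replicates, seed = NULL)
          list(xtr = enr_tr$features, ytr = enr_tr$diagnosis,
               xte = enr_te$features, yte = enr_te$diagnosis)
        },
        {
          x <- table$values
          if (protocol == "ev_only") {
            x <- x[, table$descriptors$category == "ev_marker", drop = FALSE]
          }
          sp <- stratified_split(table$diagnosis, config$train_fraction)
          list(xtr = x[sp$train, , drop = FALSE],
               ytr = table$diagnosis[sp$train],
               xte = x[sp$test, , drop = FALSE],
               yte = table$diagnosis[sp$test])
        }
      )
      if (nlevels(droplevels(res$ytr)) == 2 &&
          nlevels(droplevels(res$yte)) == 2) return(res)
    }
    stop_koaev("could not draw a split with both classes on each side",
               "koaev_degenerate_split")
  }
  run_one <- function(i) {
    rep_seed <- derive_seed(config$seed, i)
    with_seed_or_not(rep_seed, {
      d <- one_repeat()
      rseed <- sample.int(2147483646L, 1)
      fit <- fit_rf(d$xtr, d$ytr, config, rseed)
      pred <- predict(fit, data = as.data.frame(d$xte),
                      num.threads = 1)$predictions
      imp <- fit$variable.importance
      if (sum(imp) > 0) imp <- imp / sum(imp)
      list(acc = mean(pred == d$yte), imp = imp)
    })
  }
  reps <- lapply(seq_len(config$n_repeats), run_one)
  acc <- vapply(reps, `[[`, numeric(1), "acc")
  imp <- do.call(rbind, lapply(reps, `[[`, "imp"))
  mean_acc <- mean(acc)
  structure(
    list(
      protocol = protocol,
      accuracies = acc,
      mean_accuracy = mean_acc,
      importance = imp,
      importance_mean = colMeans(imp),
      importance_sd = apply(imp, 2, sd),
      importance_normalized = TRUE,
      importance_reliable = mean_acc > config$importance_accuracy_gate,
      criterion_used = "gini",
      config = config
    ),
    class = "rf_report"
  )
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("<rf_report> protocol %s: mean accuracy %.4f over %d repeats\n",
              x$protocol, x$mean_accuracy, length(x$accuracies)))
  top <- names(sort(x$importance_mean, decreasing = TRUE))[1]
  cat(sprintf("  top feature by mean decrease in impurity: %s%s\n", top,
              if (x$importance_reliable) "" else " (importance flagged unreliable: accuracy below gate)"))
  invisible(x)
}

#' Summarise feature importance across protocol reports
#'
#' Pools the per-repeat normalized mean-decrease-in-impurity scores of one
#' or more reports sharing a feature space, and ranks features by averaged
#' importance. The summary is invariant to the order of the reports; rank
#' ties are broken by feature name.
#'
#' @param reports a single `rf_report` or a list of them.
#' @return A `data.frame` with columns `feature`, `mean_importance`,
#'   `sd_importance`, `rank`, ordered by rank.
#' @export
feature_importance_summary <- function(reports) {
  if (inherits(reports, "rf_report")) reports <- list(reports)
  spaces <- lapply(reports, function(r) colnames(r$importance))
  if (length(unique(vapply(spaces, paste, character(1), collapse = "\r"))) != 1) {
    stop_koaev("reports do not share a feature space",
               "koaev_schema_mismatch")
  }
  imp <- do.call(rbind, lapply(reports, `[[`, "importance"))
  mean_imp <- colMeans(imp)
  sd_imp <- apply(imp, 2, sd)
  ord <- order(-mean_imp, colnames(imp))
  data.frame(
    feature = colnames(imp)[ord],
    mean_importance = unname(mean_imp[ord]),
    sd_importance = unname(sd_imp[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}
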