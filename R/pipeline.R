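# End-to-end orchestration: seeded runs of simulate -> EV features -> group
# statistics -> variable groups -> PCA/HC -> enrichment/RF, with a run
# manifest for reproducibility.

pipeline_stages <- c("simulate", "ev", "stats", "groups", "cluster", "rf")

#' Build a pipeline run configuration
#'
#' Exactly one of `preset` (a [koa_scenario_presets()] name) or `input`
#' (paths to cohort/descriptor CSVs) must be given. Stage seeds are derived
#' from the master seed as `seed + stage index` (stages numbered 1..6 in the
#' order simulate, ev, stats, groups, cluster, rf), so any stage can be
#' reproduced in isolation.
#'
#' @param preset preset name (`"strong_structure"`, `"null"`,
#'   `"paper_calibrated"`).
#' @param input optional list with `cohort` and optional `descriptors`,
#'   `particles`, `samples` CSV paths.
#' @param seed master seed (required; recorded in every output).
#' @param stages character vector of stages to run after data acquisition
#'   (default all of stats, groups, cluster, rf).
#' @param k,residual_threshold variable-grouping parameters.
#' @param bh_alpha false discovery rate for the statistics stage.
#' @param n_clusters flat clusters for subject clustering.
#' @param rf an [rf_protocol_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param rf_protocols protocols to run in the rf stage.
#' @param drop_variables variables removed before complete-case filtering.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input = NULL, seed = 1,
                       stages = c("stats", "groups", "cluster", "rf"),
                       k = 5, residual_threshold = 0.4, bh_alpha = 0.05,
                       n_clusters = 2, rf = rf_protocol_config(),
                       rf_protocols = c("enrich_before_split",
                                        "enrich_after_split"),
                       drop_variables = character()) {
  if (is.null(preset) == is.null(input)) {
    stop_koaev("exactly one of preset or input must be set",
               "koaev_bad_config")
  }
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    stop_koaev(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
               "koaev_bad_config")
  }
  structure(
    list(preset = preset, input = input, seed = as.integer(seed),
         stages = stages, k = k, residual_threshold = residual_threshold,
         bh_alpha = bh_alpha, n_clusters = n_clusters, rf = rf,
         rf_protocols = rf_protocols, drop_variables = drop_variables),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirror of [run_config()]; the `rf` block maps to
#' [rf_protocol_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rf <- if (is.null(y$rf)) rf_protocol_config() else
    do.call(rf_protocol_config, y$rf)
  args <- y[setdiff(names(y), "rf")]
  do.call(run_config, c(args, list(rf = rf)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order (cohort acquisition -> EV
#' features -> group statistics with FDR control -> correlation groups ->
#' PCA and subject clustering -> enrichment/RF), writing one directory of
#' CSV/JSON outputs plus `manifest.json` (configuration echo, master seed,
#' package version, and an MD5 checksum per output file). Identical
#' configuration and seed reproduce the bundle checksums exactly. A stage
#' failure aborts with the stage name; outputs of completed stages are left
#' in place.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(packageVersion("koaev")),
    stages_run = character(0),
    config = config[setdiff(names(config), "rf")]
  )
  outputs <- character(0)
  table <- NULL; truth <- NULL; evt <- NULL
  stage_seed <- function(name) derive_seed(config$seed,
                                           match(name, pipeline_stages))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_koaev(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 "koaev_stage_failure")
    })
  }
  # --- data acquisition -----------------------------------------------
  if (!is.null(config$preset)) {
    presets <- koa_scenario_presets()
    if (!config$preset %in% names(presets)) {
      stop_koaev(sprintf("unknown preset '%s'", config$preset),
                 "koaev_bad_config")
    }
    ps <- presets[[config$preset]]
    cfg <- ps$cohort
    cfg$seed <- stage_seed("simulate")
    run_stage("simulate", {
      gen <- generate_cohort(cfg)
      table <- gen$table
      truth <- gen$truth
      write_cohort(table, file.path(out_dir, "cohort.csv"),
                   file.path(out_dir, "descriptors.csv"))
      write.csv(truth, file.path(out_dir, "planted_truth.csv"),
                row.names = FALSE)
      evt <- size_gate(
        generate_ev_particles(ps$ev_sev, table$subjects,
                              seed = stage_seed("ev")),
        "sEV"
      )
      outputs <- c(outputs, "cohort.csv", "descriptors.csv",
                    "planted_truth.csv")
      manifest$stages_run <- c(manifest$stages_run, "simulate")
    })
  } else {
    run_stage("load", {
      table <- read_cohort(config$input$cohort, config$input$descriptors)
      truth <- NULL
      evt <- if (!is.null(config$input$particles)) {
        size_gate(read_ev_particles(config$input$particles,
                                    config$input$samples), "sEV")
      } else NULL
    })
  }
  # --- EV features ----------------------------------------------------
  if ("ev" %in% config$stages && !is.null(evt)) {
    run_stage("ev", {
      feats <- cohort_ev_features(evt, table$subjects)
      table <- add_ev_features(table, feats)
      write.csv(as.data.frame(feats), file.path(out_dir, "ev_features.csv"))
      outputs <- c(outputs, "ev_features.csv")
      manifest$stages_run <- c(manifest$stages_run, "ev")
    })
  }
  analysed <- complete_case_filter(table, config$drop_variables)
  ztab <- z_score(analysed)
  # --- univariate statistics ------------------------------------------
  if ("stats" %in% config$stages) {
    run_stage("stats", {
      st <- cohort_group_stats(table, alpha = config$bh_alpha)
      write.csv(st, file.path(out_dir, "group_stats.csv"), row.names = FALSE)
      outputs <- c(outputs, "group_stats.csv")
      manifest$stages_run <- c(manifest$stages_run, "stats")
      manifest$bh_critical_value <- attr(st, "fdr_report")$critical_value
    })
  }
  # --- variable groups ------------------------------------------------
  groups <- NULL
  if (any(c("groups", "rf") %in% config$stages)) {
    run_stage("groups", {
      cm <- correlation_matrix(ztab)
      groups <- cluster_variables(cm, k = config$k,
                                   residual_threshold = config$residual_threshold)
      write.csv(as.data.frame(groups),
                file.path(out_dir, "variable_groups.csv"), row.names = FALSE)
      group_correlogram_export(cm, groups,
                               file.path(out_dir, "correlogram.csv"))
      outputs <- c(outputs, "variable_groups.csv", "correlogram.csv",
                    "correlogram_stars.csv")
      manifest$stages_run <- c(manifest$stages_run, "groups")
    })
  }
  # --- unsupervised classification ------------------------------------
  if ("cluster" %in% config$stages) {
    run_stage("cluster", {
      pca <- pca_subjects(ztab)
      write.csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
      write.csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
      sc <- cluster_subjects(ztab, n_clusters = config$n_clusters)
      export_tree_newick(sc, file.path(out_dir, "subject_tree.nwk"))
      outputs <- c(outputs, "pca_scores.csv", "pca_loadings.csv",
                    "subject_tree.nwk")
      manifest$stages_run <- c(manifest$stages_run, "cluster")
      manifest$cluster_ari <- sc$ari
      manifest$cluster_purity <- sc$purity
      manifest$pc12_variance <- sum(pca$explained_variance[1:2])
    })
  }
  # --- enrichment / random forest -------------------------------------
  if ("rf" %in% config$stages) {
    run_stage("rf", {
      rf_cfg <- config$rf
      rf_cfg$seed <- stage_seed("rf")
      reports <- lapply(config$rf_protocols, function(pr) {
        rr <- run_protocol(ztab, groups, rf_cfg, pr)
        list(
          protocol = rr$protocol,
          mean_accuracy = rr$mean_accuracy,
          accuracies = rr$accuracies,
          importance_mean = as.list(rr$importance_mean),
          importance_sd = as.list(rr$importance_sd),
          importance_reliable = rr$importance_reliable,
          criterion_used = rr$criterion_used
        )
      })
      names(reports) <- config$rf_protocols
      jsonlite::write_json(
        list(seed = rf_cfg$seed,
             config = rf_cfg[setdiff(names(rf_cfg), "seed")],
             reports = reports),
        file.path(out_dir, "rf_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      outputs <- c(outputs, "rf_report.json")
      manifest$stages_run <- c(manifest$stages_run, "rf")
      manifest$rf_mean_accuracy <- setNames(
        lapply(reports, `[[`, "mean_accuracy"), names(reports))
    })
  }
  manifest$checksums <- as.list(md5sum(file.path(out_dir, sort(outputs))))
  names(manifest$checksums) <- sort(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
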