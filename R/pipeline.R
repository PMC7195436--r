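# End-to-end orchestration: simulate -> features -> rhythms/synchrony ->
# forecasts -> clusters, with provenance and JSON/CSV report bundling.

#' Pipeline configuration
#'
#' @param seed Top-level seed; every stochastic stage derives its stream
#'   from it.
#' @param sim Named list of [sim_config()] overrides.
#' @param stages Character vector of stages to run, in dependency order
#'   subset of `c("simulate", "features", "synchrony", "forecast",
#'   "clusters")`.
#' @param methods Forecast methods: subset of `c("m1", "m2", "random")`.
#' @param n_markov Markov chance realizations.
#' @param out_dir Optional output directory for report files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = list(),
                            stages = c("simulate", "features", "synchrony",
                                       "forecast", "clusters"),
                            methods = c("m1", "m2", "random"),
                            n_markov = 100, out_dir = NULL) {
  structure(list(seed = seed, sim = sim, stages = stages, methods = methods,
                 n_markov = n_markov, out_dir = out_dir),
            class = "pipeline_config")
}

stage_fail <- function(stage, e) {
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full analysis pipeline on a synthetic recording
#'
#' Executes the enabled stages in dependency order. Every report carries
#' the config hash; rerunning with an identical config is bit-identical.
#'
#' @param config A [pipeline_config()] (or plain list with its fields).
#' @return List of class `report_bundle` with the stage outputs that were
#'   produced: `recording`, `features`, `si`, `m1`, `m2`, `random`,
#'   `clusters`, `summary`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- config$stages
  hash <- config_hash(config[c("seed", "sim", "stages", "methods")])
  out <- list(config_hash = hash, config = config)

  scfg <- tryCatch(do.call(sim_config, c(config$sim, list(seed = config$seed))),
                   error = function(e) stage_fail("config", e))
  if ("simulate" %in% stages) {
    out$recording <- tryCatch(simulate_recording(scfg),
                              error = function(e) stage_fail("simulate", e))
  }
  if ("features" %in% stages) {
    out$features <- tryCatch(
      extract_features(out$recording$segments, template = scfg$spike_template),
      error = function(e) stage_fail("features", e))
  }
  onsets <- out$recording$seizure_catalog$onset_h
  if ("synchrony" %in% stages) {
    out$si <- tryCatch(
      si_table(out$features, onsets, causal = TRUE, seed = config$seed),
      error = function(e) stage_fail("synchrony", e))
  }
  if ("forecast" %in% stages) {
    if ("m1" %in% config$methods)
      out$m1 <- tryCatch(
        forecast_m1(out$features, out$recording$seizure_catalog,
                    seed = config$seed),
        error = function(e) stage_fail("forecast_m1", e))
    if ("m2" %in% config$methods)
      out$m2 <- tryCatch(
        forecast_m2(out$features, out$recording$seizure_catalog,
                    seed = config$seed),
        error = function(e) stage_fail("forecast_m2", e))
    if ("random" %in% config$methods && !is.null(out$m1))
      out$random <- tryCatch(
        random_markov_predictor(out$m1$risk$level,
                                prior_sample_index(out$features$times_h, onsets),
                                n_sims = config$n_markov, seed = config$seed),
        error = function(e) stage_fail("forecast_random", e))
  }
  if ("clusters" %in% stages) {
    ch <- if (!is.null(out$si)) {
      v <- out$si$si[, "acfw.long"]
      if (all(!is.finite(v))) 1L else which.max(ifelse(is.finite(v), v, -Inf))
    } else 1L
    out$clusters <- tryCatch(
      cluster_analysis(out$features, out$recording$seizure_catalog,
                       channel = ch),
      error = function(e) stage_fail("clusters", e))
  }
  out$summary <- summarize_bundle(out)
  if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
  structure(out, class = "report_bundle")
}

summarize_bundle <- function(out) {
  row <- list(config_hash = out$config_hash,
              n_seizures = nrow(out$recording$seizure_catalog),
              missing_fraction = mean(out$recording$segments$mask))
  for (m in c("m1", "m2")) {
    r <- out[[m]]$report
    if (!is.null(r)) {
      row[[paste0(m, "_seizure_high")]] <- unname(r$seizure_fraction["high"])
      row[[paste0(m, "_time_low")]] <- unname(r$time_fraction["low"])
      row[[paste0(m, "_performance_product")]] <- unname(r$performance_product)
      row[[paste0(m, "_mean_risk")]] <- r$mean_risk_level
    }
  }
  if (!is.null(out$random))
    row$random_product_q975 <-
      unname(stats::quantile(out$random$sims$performance_product, 0.975))
  as.data.frame(row)
}

write_bundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_seizure_catalog(out$recording$seizure_catalog,
                        file.path(dir, "seizure_catalog.csv"))
  if (!is.null(out$features))
    write_feature_series(out$features, file.path(dir, "features.csv"))
  keep_report <- function(x) {
    x$roc <- NULL
    x
  }
  js <- list(config_hash = out$config_hash)
  if (!is.null(out$si)) js$si <- out$si$si
  if (!is.null(out$m1)) js$m1 <- keep_report(unclass(out$m1$report))
  if (!is.null(out$m2)) js$m2 <- keep_report(unclass(out$m2$report))
  if (!is.null(out$random)) {
    js$random <- list(
      transition = out$random$transition,
      performance_product_q = stats::quantile(
        out$random$sims$performance_product, c(0.025, 0.5, 0.975)))
  }
  if (!is.null(out$clusters)) {
    cl <- out$clusters
    js$clusters <- list(has_clusters = cl$has_clusters,
                        lead_time_d = cl$lead_time_d, n_lead = cl$n_lead)
    if (isTRUE(cl$has_clusters))
      utils::write.csv(
        data.frame(rel_time_h = cl$rel_time_h,
                   mean_acfw = cl$mean_acfw, se_acfw = cl$se_acfw,
                   mean_var = cl$mean_var, se_var = cl$se_var,
                   follower_density = cl$follower_density),
        file.path(dir, "cluster_profiles.csv"), row.names = FALSE)
  }
  jsonlite::write_json(js, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  utils::write.csv(out$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Cross-run summary table
#'
#' Binds the one-row summaries of several pipeline bundles; optionally
#' compares a metric between two method columns with a paired Wilcoxon
#' test (thin wrapper over standard routines).
#'
#' @param bundles List of `report_bundle`s (>= 1).
#' @return data.frame, one row per run.
#' @export
summarize_runs <- function(bundles) {
  if (length(bundles) == 0) stop("no reports to summarize")
  rows <- lapply(bundles, function(b) {
    if (!is.null(b$summary)) b$summary else stop("schema mismatch: not a report bundle")
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}
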