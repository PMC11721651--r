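#' Pipeline configuration
#'
#' Collects every analysis constant as an explicit, overridable parameter,
#' with the standard values as defaults: 0.05 uS specific-response
#' threshold, 1.5 s post-gesture latency pad, 1.5 s quote-assignment
#' tolerance, resonance at >= 2 concurrent specific responses, and a
#' 1,500-tree / mtry 3 forest. Input is either a directory of tabular-tier
#' annotations plus EDA CSVs, or a [sim_config()] for a simulate-then-analyze
#' run.
#'
#' @param input path to a corpus directory (tabular dialect + `eda_*.csv`),
#'   or `NULL` when simulating
#' @param sim a [sim_config()], or `NULL` when reading from disk
#' @param threshold specific-response threshold, uS (> 0)
#' @param latency_pad post-gesture window extension, seconds (>= 0)
#' @param quote_tolerance fuzzy quote distance, seconds
#' @param resonance_min minimum concurrent specific responses (>= 1;
#'   the standard resonance definition uses 2)
#' @param require_narrator must the narrator be among the responders?
#' @param ntree,mtry forest settings
#' @param importance_reps permutations per predictor for importance
#' @param seed master seed for all stochastic stages
#' @param out_dir optional output directory for JSON/CSV artifacts
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(input = NULL, sim = NULL, threshold = 0.05,
                            latency_pad = 1.5, quote_tolerance = 1.5,
                            resonance_min = 2, require_narrator = FALSE,
                            ntree = 1500, mtry = 3, importance_reps = 10,
                            seed = 1L, out_dir = NULL) {
  if (is.null(input) && is.null(sim)) {
    stop_ctx("either input or sim must be given", class = "config_error")
  }
  if (threshold <= 0) stop_ctx("threshold must be > 0", class = "config_error")
  if (latency_pad < 0) stop_ctx("latency_pad must be >= 0", class = "config_error")
  if (resonance_min < 1) stop_ctx("resonance_min must be >= 1", class = "config_error")
  structure(list(input = input, sim = sim, threshold = threshold,
                 latency_pad = latency_pad, quote_tolerance = quote_tolerance,
                 resonance_min = resonance_min,
                 require_narrator = require_narrator,
                 ntree = ntree, mtry = mtry,
                 importance_reps = importance_reps,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; a `sim:` mapping is
#' forwarded to [sim_config()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

read_corpus_dir <- function(path) {
  ann <- read_annotations(path, dialect = "tabular")
  eda_files <- list.files(path, pattern = "^eda_.*\\.csv$", full.names = TRUE)
  traces <- lapply(eda_files, read_eda)
  names(traces) <- vapply(traces, `[[`, character(1), "participant_id")
  list(ann = ann, traces = traces, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Stages: ingest (or simulate) -> feature derivation -> EDA outcomes ->
#' crescendo model (RQ1) -> arousal model (RQ2) -> resonance forest with
#' permutation importance and fit metrics (RQ3). Every stage logs its
#' record counts; gestures dropped at the EDA stage are listed in the
#' exclusion log. Fully reproducible given the config seed; if `out_dir` is
#' set, the feature table (CSV), model results (JSON) and the resolved
#' configuration are written there.
#'
#' @param cfg a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return object of class `pipeline_result` with elements `features`,
#'   `responses`, `excluded`, `rq1`, `rq2`, `rf`, `importance`, `metrics`,
#'   `truth` (simulations only) and `config`
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  corpus <- if (!is.null(cfg$sim)) {
    say("stage simulate: %d recording(s)", cfg$sim$n_recordings)
    sim <- simulate_corpus(cfg$sim)
    list(ann = sim$ann, traces = sim$traces, truth = sim$truth)
  } else {
    say("stage ingest: %s", cfg$input)
    read_corpus_dir(cfg$input)
  }
  ann <- corpus$ann
  say("stage ingest: %d stories, %d gestures, %d traces",
      nrow(ann$stories), nrow(ann$gestures), length(corpus$traces))

  features <- build_features(ann, quote_tolerance = cfg$quote_tolerance)
  say("stage features: %d gesture records", nrow(features))

  eda <- add_eda_outcomes(features, ann$gestures, corpus$traces,
                          ann$participants, threshold = cfg$threshold,
                          latency_pad = cfg$latency_pad,
                          min_specific = cfg$resonance_min,
                          require_narrator = cfg$require_narrator)
  n_ok <- sum(!is.na(eda$features$EDA_G_resonance))
  say("stage eda: %d gestures scored, %d excluded", n_ok, nrow(eda$excluded))

  analysed <- eda$features[!is.na(eda$features$EDA_G_resonance), , drop = FALSE]
  rq2_records <- merge(
    eda$responses,
    analysed[, c("gesture_id", "G_expressivity")], by = "gesture_id")

  rq1 <- fit_rq1(analysed)
  say("stage rq1: LRT chisq = %.2f (df %d), p = %.3g",
      rq1$lrt$chisq, rq1$lrt$df, rq1$lrt$p)
  rq2_records$specific <- as.integer(rq2_records$specific)
  rq2 <- fit_rq2(rq2_records)
  say("stage rq2: LRT chisq = %.2f (df %d), p = %.3g",
      rq2$lrt$chisq, rq2$lrt$df, rq2$lrt$p)

  rf <- fit_rq3_rf(analysed, seed = derive_seed(cfg$seed, 31L),
                   ntree = cfg$ntree, mtry = cfg$mtry)
  imp <- permutation_importance(rf, reps = cfg$importance_reps,
                                seed = derive_seed(cfg$seed, 32L))
  metrics <- fit_metrics(rf)
  say("stage rq3: OOB accuracy %.3f (baseline %.3f), top predictor %s",
      metrics$accuracy, metrics$baseline, imp$predictor[1])

  res <- structure(
    list(features = eda$features, responses = eda$responses,
         excluded = eda$excluded, rq2_records = rq2_records,
         rq1 = rq1, rq2 = rq2, rf = rf, importance = imp, metrics = metrics,
         truth = corpus$truth, config = cfg),
    class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

result_json <- function(res) {
  cfg <- res$config
  list(
    config = list(threshold = cfg$threshold, latency_pad = cfg$latency_pad,
                  quote_tolerance = cfg$quote_tolerance,
                  resonance_min = cfg$resonance_min,
                  require_narrator = cfg$require_narrator,
                  ntree = cfg$ntree, mtry = cfg$mtry, seed = cfg$seed),
    counts = list(gestures = nrow(res$features),
                  scored = sum(!is.na(res$features$EDA_G_resonance)),
                  excluded = nrow(res$excluded),
                  resonant = sum(res$features$EDA_G_resonance, na.rm = TRUE)),
    rq1 = list(fixed = res$rq1$fixed, lrt = res$rq1$lrt,
               r2_conditional = res$rq1$r2_conditional,
               prop_positive_slope = res$rq1$prop_positive,
               fallback_random_intercepts = res$rq1$fallback),
    rq2 = list(fixed = res$rq2$fixed, lrt = res$rq2$lrt,
               r2_conditional = res$rq2$r2_conditional),
    rq3 = list(settings = list(ntree = res$rf$ntree, mtry = res$rf$mtry),
               metrics = res$metrics[c("r2_traditional", "r2_mcfadden",
                                       "binomial_p", "accuracy", "baseline")],
               importance = res$importance,
               importance_method = attr(res$importance, "method")))
}

#' Write pipeline artifacts
#'
#' Feature table as CSV and the model results (with the resolved
#' configuration embedded for provenance) as JSON.
#'
#' @param res a `pipeline_result`
#' @param path output directory
#' @export
write_pipeline_outputs <- function(res, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(res$features, file.path(path, "feature_table.csv"))
  if (!is.null(res$excluded) && nrow(res$excluded)) {
    utils::write.csv(res$excluded, file.path(path, "excluded.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result_json(res), file.path(path, "results.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  gestures: %d (%d resonant, %d excluded)\n",
              nrow(x$features),
              sum(x$features$EDA_G_resonance, na.rm = TRUE),
              nrow(x$excluded)))
  cat(sprintf("  RQ1 crescendo: slope %.4f, LRT p = %.3g, R2c = %.3f\n",
              x$rq1$fixed$estimate[x$rq1$fixed$term == "G_position_rel"],
              x$rq1$lrt$p, x$rq1$r2_conditional))
  cat(sprintf("  RQ2 arousal:   slope %.4f, LRT p = %.3g, R2c = %.3f\n",
              x$rq2$fixed$estimate[x$rq2$fixed$term == "G_expressivity"],
              x$rq2$lrt$p, x$rq2$r2_conditional))
  cat(sprintf("  RQ3 forest:    OOB acc %.3f (baseline %.3f), McFadden R2 %.3f\n",
              x$metrics$accuracy, x$metrics$baseline, x$metrics$r2_mcfadden))
  cat(sprintf("  top predictors: %s\n",
              paste(utils::head(x$importance$predictor, 3), collapse = ", ")))
  invisible(x)
}
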