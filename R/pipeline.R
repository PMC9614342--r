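#' Pipeline configuration
#'
#' Bundles the three stage configurations with the analysis-level
#' settings. All defaults reproduce the analysis constants (60 s trim,
#' 2-SD arm filter, 25-frame gap threshold, 50-frame minimum chunk,
#' 3-step minimum, seven 10-degree straightness bins over +/-35 degrees,
#' alpha = 0.05); the master seed drives every per-trial substream.
#'
#' @param seed Master integer seed.
#' @param cohort A [cohort_config()]; its seed is replaced by `seed`.
#' @param walk A [walk_config()] of per-trial defaults.
#' @param params Feature-extraction parameters ([feature_params()]).
#' @param alpha Significance level for screening and flagging.
#' @param ss_type Sums-of-squares type for the multi-factor ANOVA (2 or 3).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = NULL,
                            walk = walk_config(),
                            params = feature_params(),
                            alpha = 0.05, ss_type = 2) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), cohort = cohort, walk = walk,
                 params = params, alpha = alpha, ss_type = ss_type),
            class = "pipeline_config")
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Generates (or ingests) a cohort, extracts features trial by trial,
#' runs the emotion-effect statistics, and writes every result table plus
#' a manifest of output files with content hashes. Corrupted trials are
#' counted as ingested but excluded from analysis.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param series Optional named list of [marker_series()] to analyse
#'   instead of generating trials (names must match `meta$trial_id`).
#' @param meta Optional metadata to use with `series`.
#' @param verbose Print per-trial progress.
#' @return A list: `meta`, `features`, `arm_swing`, `qc`, `anova_oneway`,
#'   `tukey`, `anova_multifactor`, `regression`, `report`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         series = NULL, meta = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(series)) {
    cohort <- generate_cohort(cfg$cohort, cfg$walk, materialize = FALSE)
    meta <- cohort$meta
    get_series <- function(k) {
      generate_trial(cohort$walks[[k]], meta[k, , drop = FALSE],
                     trim_guard_s = cfg$params$trim_seconds)
    }
  } else {
    stopifnot(!is.null(meta), nrow(meta) == length(series))
    get_series <- function(k) series[[meta$trial_id[k]]]
  }

  n_trials <- nrow(meta)
  usable <- which(!meta$corrupted)
  feat_list <- list()
  qc_list <- list()
  for (k in usable) {
    s <- get_series(k)
    res <- suppressWarnings(extract_trial_features(s, cfg$params))
    feat_list[[length(feat_list) + 1L]] <- res$features
    qc <- res$qc
    qc$direction <- res$direction
    qc_list[[length(qc_list) + 1L]] <- as.data.frame(qc,
                                                    stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("[%s] frames=%d chunks=%d steps=%d direction=%s",
                      qc$trial_id, qc$n_frames_trimmed,
                      qc$n_chunks_straightness, qc$n_steps, res$direction))
    }
  }
  features <- do.call(rbind, feat_list)
  qc <- do.call(rbind, qc_list)

  arm_swing <- build_arm_swing_table(features, meta)
  oneway <- list(
    reported = one_way_anova(features, meta, "reported_emotion"),
    expected = one_way_anova(features, meta, "expected_emotion")
  )
  tukey <- list(
    reported = tukey_screen(oneway$reported, features, meta, cfg$alpha),
    expected = tukey_screen(oneway$expected, features, meta, cfg$alpha)
  )
  multifactor <- tryCatch(
    multi_factor_anova(arm_swing, cfg$ss_type),
    error = function(e) {
      warning("multi-factor ANOVA skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    }
  )
  regression <- suppressWarnings(fit_curvature_regression(arm_swing))
  report <- build_report(oneway, tukey, multifactor, regression,
                         arm_swing, cfg$alpha)
  report$counts <- list(trials_ingested = n_trials,
                        trials_analyzed = length(usable))

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      metadata = file.path(out_dir, "metadata.csv"),
      features = file.path(out_dir, "features.csv"),
      arm_swing = file.path(out_dir, "arm_swing.csv"),
      qc = file.path(out_dir, "qc.csv"),
      anova_oneway = file.path(out_dir, "anova_oneway.csv"),
      tukey = file.path(out_dir, "tukey.csv"),
      anova_multifactor = file.path(out_dir, "anova_multifactor.csv"),
      regression = file.path(out_dir, "regression.csv"),
      report = file.path(out_dir, "report.json")
    )
    write_trial_metadata(meta, paths["metadata"])
    data.table::fwrite(features, paths["features"])
    data.table::fwrite(arm_swing, paths["arm_swing"])
    data.table::fwrite(qc, paths["qc"])
    data.table::fwrite(rbind(oneway$reported, oneway$expected),
                       paths["anova_oneway"])
    data.table::fwrite(rbind(tukey$reported, tukey$expected),
                       paths["tukey"])
    data.table::fwrite(
      if (is.null(multifactor)) {
        data.frame(term = character(0), df = integer(0),
                   F = numeric(0), p = numeric(0))
      } else multifactor,
      paths["anova_multifactor"])
    data.table::fwrite(regression, paths["regression"])
    write_report(report, paths["report"])
    manifest <- data.frame(
      name = names(paths), path = unname(paths),
      md5 = unname(tools::md5sum(unname(paths))),
      stringsAsFactors = FALSE
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }

  list(meta = meta, features = features, arm_swing = arm_swing, qc = qc,
       anova_oneway = oneway, tukey = tukey,
       anova_multifactor = multifactor, regression = regression,
       report = report, manifest = manifest)
}
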