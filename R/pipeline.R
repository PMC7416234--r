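#' Run the full selection-classification pipeline
#'
#' End-to-end orchestration: downsample the raw trials to the analysis
#' rate, extract MST power-spectral-density features, run the configured
#' selection scheme (multilevel channel and/or feature PSO, or none for the
#' unoptimized baseline), refit the Bayesian discriminant on all training
#' trials with the final mask, and score the held-out trials with the full
#' metric suite. Optionally writes every artifact (config snapshot,
#' per-level masks and reports, fitness trace, final model) to an output
#' directory; identical config + seed + input reproduce those files byte
#' for byte.
#'
#' @param train Training [trial_tensor()].
#' @param test Held-out [trial_tensor()], or `NULL` to carve a stratified
#'   holdout of `config$holdout_frac` out of `train` (seeded by
#'   `config$seed`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `pipeline_result`: `scheme`, `selection` (the
#'   `mlpso_result`/`mlpso_cf_result`, or `NULL` for scheme `"none"`),
#'   `final_model` ([blda()]), `final_report` ([evaluate_classification()]
#'   output on the held-out set), `selected_columns`, `n_features_used`,
#'   `n_evals`, `config`.
#' @examples
#' \donttest{
#' tt <- make_fixture("tiny", seed = 2)
#' cfg <- pipeline_config(scheme = "feature", n_particles = 10, n_iter = 10,
#'                        max_level = 2, seed = 2)
#' res <- run_pipeline(tt, config = cfg)
#' glance(res$final_report)
#' }
#' @export
run_pipeline <- function(train, test = NULL, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(train, "trial_tensor"), inherits(config, "pipeline_config"))
  if (is.null(test)) {
    sp <- stratified_split(train$labels, config$holdout_frac, config$seed)
    test <- subset_trials(train, sp$eval)
    train <- subset_trials(train, sp$train)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  mcfg <- mst_config(config$p, config$q, config$f_min, config$f_max, config$f_step)
  pcfg <- pso_config(config$n_particles, config$n_iter, config$c1, config$c2,
                     config$w_max, config$w_min, config$v_max, config$seed)

  train <- stage("downsample", downsample_trials(train, config$analysis_fs))
  test <- stage("downsample", downsample_trials(test, config$analysis_fs))
  ftr <- stage("extract_features", extract_features(train, mcfg))
  fte <- stage("extract_features", extract_features(test, mcfg))

  selection <- NULL
  cols <- seq_len(ncol(ftr$values))
  if (config$scheme == "channel") {
    selection <- stage("selection", run_multilevel(
      ftr, "channel", pcfg, config$max_level, holdout = fte,
      split_frac = config$split_frac, fitness_on_holdout = config$fitness_on_holdout,
      use_scores = config$use_scores, n_folds = config$n_folds))
    chans <- selection$levels[[length(selection$levels)]]$selected
    cols <- which(ftr$columns$channel %in% chans)
  } else if (config$scheme == "feature") {
    selection <- stage("selection", run_multilevel(
      ftr, "feature", pcfg, config$max_level, holdout = fte,
      split_frac = config$split_frac, fitness_on_holdout = config$fitness_on_holdout,
      use_scores = config$use_scores, n_folds = config$n_folds))
    cols <- selection$levels[[length(selection$levels)]]$selected
  } else if (config$scheme == "channel-feature") {
    selection <- stage("selection", channel_then_feature(
      ftr, pcfg, pcfg, config$max_level, config$max_level, holdout = fte,
      split_frac = config$split_frac, fitness_on_holdout = config$fitness_on_holdout,
      use_scores = config$use_scores, n_folds = config$n_folds))
    cols <- selection$selected_columns
  }

  final_model <- stage("final_fit", blda(
    ftr$values[, cols, drop = FALSE], ftr$labels,
    standardize = config$standardize, target_coding = config$target_coding))
  pr <- predict(final_model, fte$values[, cols, drop = FALSE])
  final_report <- evaluate_classification(fte$labels, pr$label)

  result <- structure(
    list(scheme = config$scheme, selection = selection,
         final_model = final_model, final_report = final_report,
         selected_columns = cols, n_features_used = length(cols),
         columns = ftr$columns,
         n_evals = if (is.null(selection)) 0L else selection$n_evals,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(result$config, file.path(out_dir, "config.json"))
  write_report_json <- function(report, path) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  }
  dump_levels <- function(ml, prefix = "level") {
    traces <- list()
    for (lv in ml$levels) {
      d <- file.path(out_dir, sprintf("%s_%d", prefix, lv$level))
      dir.create(d, showWarnings = FALSE)
      bits <- if (ml$granularity == "channel") {
        chans <- sort(unique(ml$columns$channel))
        as.integer(chans %in% lv$selected)
      } else {
        as.integer(ml$columns$column %in% lv$selected)
      }
      cols_meta <- if (ml$granularity == "channel") NULL else ml$columns
      write_mask(bits, file.path(d, "mask.txt"), columns = cols_meta)
      if (!is.null(lv$report)) write_report_json(lv$report, file.path(d, "report.json"))
      traces[[lv$level]] <- dplyr::mutate(lv$trace, level = lv$level)
    }
    dplyr::bind_rows(traces)
  }
  trace <- NULL
  if (inherits(result$selection, "mlpso_result")) {
    trace <- dump_levels(result$selection)
  } else if (inherits(result$selection, "mlpso_cf_result")) {
    trace <- dplyr::bind_rows(
      dplyr::mutate(dump_levels(result$selection$channel, "channel_level"), phase = "channel"),
      dplyr::mutate(dump_levels(result$selection$feature, "feature_level"), phase = "feature")
    )
  }
  if (!is.null(trace)) {
    utils::write.table(trace, file.path(out_dir, "trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_report_json(result$final_report, file.path(out_dir, "final_report.json"))
  write_blda(result$final_model, file.path(out_dir, "final_model.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> scheme = %s; %d feature(s) used; %d fitness evaluations\n",
              x$scheme, x$n_features_used, x$n_evals))
  print(x$final_report)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble: scheme, features used, fitness evaluations, and the
#'   held-out metric suite.
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scheme = x$scheme, n_features_used = x$n_features_used,
                   n_evals = x$n_evals),
    glance.eval_report(x$final_report)
  )
}
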