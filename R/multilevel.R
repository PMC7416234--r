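#' Multilevel binary PSO selection
#'
#' Runs the binary particle swarm optimizer repeatedly: level 1 searches
#' the full channel or feature space; each subsequent level searches only
#' the coordinates its predecessor's global best selected, with a fresh,
#' independently seeded swarm on the re-indexed (smaller) space. The loop
#' stops when `max_level` is reached or when two consecutive levels select
#' the same number of coordinates — the sign that the task-related subset
#' has stabilised. Restarting on the shrunken space is what lets the
#' optimizer escape the stagnation of a single swarm whose particles have
#' collapsed onto one position.
#'
#' @param features Training `feature_matrix` (see [extract_features()]).
#' @param granularity `"feature"`: mask bits are feature columns;
#'   `"channel"`: mask bits are channels, and a set channel activates its
#'   whole block of per-frequency columns.
#' @param cfg A [pso_config()]. Level `k` runs with seed `cfg$seed + k`, so
#'   levels use independent initial swarms while the whole procedure stays
#'   reproducible.
#' @param max_level Maximum number of levels (>= 1).
#' @param holdout Optional held-out `feature_matrix`; each level's selection
#'   is refitted on all training trials and scored on it
#'   (see [evaluate_classification()]).
#' @param split_frac Fraction of training trials used as the internal
#'   validation split of the wrapper fitness.
#' @param fitness_on_holdout If `TRUE`, the wrapper fitness is computed on
#'   `holdout` itself instead of an internal split (the protocol that lets
#'   evaluation labels steer selection; off by default).
#' @param use_scores,n_folds Passed to [selection_fitness()].
#' @return An object of class `mlpso_result`: a list of per-level results
#'   (`level`, `selected` indices in the original space, `n_selected`,
#'   `fitness`, `trace`, `n_evals`, `report`), plus metadata. Selections are
#'   nested across levels. See [tidy.mlpso_result()], [autoplot.mlpso_result()]
#'   and [channel_report()].
#' @examples
#' tt <- make_fixture("tiny", seed = 1)
#' fm <- extract_features(tt)
#' cfg <- pso_config(n_particles = 10, n_iter = 5, seed = 1)
#' res <- run_multilevel(fm, "channel", cfg, max_level = 2)
#' tidy(res)
#' @export
run_multilevel <- function(features, granularity = c("feature", "channel"),
                           cfg = pso_config(), max_level = 10, holdout = NULL,
                           split_frac = 0.25, fitness_on_holdout = FALSE,
                           use_scores = FALSE, n_folds = 1L) {
  stopifnot(inherits(features, "feature_matrix"), inherits(cfg, "pso_config"))
  granularity <- match.arg(granularity)
  if (max_level < 1) stop("`max_level` must be >= 1", call. = FALSE)
  if (fitness_on_holdout && is.null(holdout)) {
    stop("`fitness_on_holdout = TRUE` requires an explicit `holdout` evaluation set", call. = FALSE)
  }
  active <- if (granularity == "channel") {
    sort(unique(features$columns$channel))
  } else {
    seq_len(ncol(features$values))
  }
  eval_features <- if (fitness_on_holdout) holdout else NULL

  levels <- list()
  prev_n <- NA_integer_
  for (lv in seq_len(max_level)) {
    if (length(active) < 1L) stop("selection space is empty", call. = FALSE)
    cfg_lv <- cfg
    cfg_lv$seed <- cfg$seed + lv
    fitness <- selection_fitness(features, granularity, active = active,
                                 eval_features = eval_features,
                                 split_frac = split_frac, seed = cfg$seed,
                                 use_scores = use_scores, n_folds = n_folds)
    res <- run_bpso(length(active), fitness, cfg_lv)
    selected <- active[res$mask == 1L]
    report <- if (!is.null(holdout)) {
      evaluate_selection(features, holdout, selected, granularity)
    } else {
      NULL
    }
    levels[[lv]] <- list(
      level = lv, granularity = granularity, selected = selected,
      n_selected = length(selected), fitness = res$fitness,
      trace = res$trace, n_evals = res$n_evals, report = report
    )
    if (!is.na(prev_n) && length(selected) == prev_n) break
    prev_n <- length(selected)
    active <- selected
  }
  structure(
    list(levels = levels, granularity = granularity,
         columns = features$columns, config = cfg,
         n_evals = sum(vapply(levels, `[[`, integer(1), "n_evals"))),
    class = "mlpso_result"
  )
}

# refit on all training rows with the selected coordinates and score the
# held-out set
evaluate_selection <- function(features, holdout, selected, granularity) {
  cols <- if (granularity == "channel") {
    which(features$columns$channel %in% selected)
  } else {
    selected
  }
  fit <- blda(features$values[, cols, drop = FALSE], features$labels)
  pr <- predict(fit, holdout$values[, cols, drop = FALSE])
  evaluate_classification(holdout$labels, pr$label)
}

#' Channel selection with multilevel PSO
#'
#' [run_multilevel()] at channel granularity: particles have one bit per
#' channel, and a set bit includes that channel's whole per-frequency
#' feature block in the wrapper fitness.
#'
#' @inheritParams run_multilevel
#' @param ... Passed to [run_multilevel()].
#' @return An `mlpso_result` whose `selected` entries are channel indices.
#' @export
channel_selection <- function(features, cfg = pso_config(), max_level = 10, ...) {
  run_multilevel(features, "channel", cfg, max_level, ...)
}

#' Feature selection with multilevel PSO
#'
#' [run_multilevel()] at feature granularity: one particle bit per
#' (channel, frequency) column.
#'
#' @inheritParams run_multilevel
#' @param ... Passed to [run_multilevel()].
#' @return An `mlpso_result` whose `selected` entries are feature-column
#'   indices.
#' @export
feature_selection <- function(features, cfg = pso_config(), max_level = 10, ...) {
  run_multilevel(features, "feature", cfg, max_level, ...)
}

#' Channel-then-feature selection
#'
#' The combined scheme: multilevel channel selection first eliminates
#' task-irrelevant channels; the feature matrix is then restricted to the
#' surviving channels and multilevel feature selection refines the subset
#' within them. Channel screening shrinks the feature search space (each
#' dropped channel removes a whole frequency block), so the feature phase
#' spends far fewer classifier fits reaching the same selection quality as
#' feature-only search on the full space.
#'
#' @param features Training `feature_matrix`.
#' @param cfg_channel,cfg_feature [pso_config()]s for the two phases.
#' @param max_level_channel,max_level_feature Level caps per phase.
#' @param holdout Optional held-out `feature_matrix` for per-level reports.
#' @param ... Passed to both [run_multilevel()] calls.
#' @return An object of class `mlpso_cf_result` with elements `channel`
#'   (phase-1 `mlpso_result`), `feature` (phase-2 `mlpso_result` on the
#'   restricted matrix), `selected_channels`, `selected_columns` (indices
#'   into the original feature space) and `n_evals`.
#' @export
channel_then_feature <- function(features, cfg_channel = pso_config(),
                                 cfg_feature = pso_config(),
                                 max_level_channel = 10, max_level_feature = 10,
                                 holdout = NULL, ...) {
  ch <- run_multilevel(features, "channel", cfg_channel, max_level_channel,
                       holdout = holdout, ...)
  chans <- ch$levels[[length(ch$levels)]]$selected
  restricted <- select_channels(features, chans)
  restricted_holdout <- if (!is.null(holdout)) select_channels(holdout, chans) else NULL
  ft <- run_multilevel(restricted, "feature", cfg_feature, max_level_feature,
                       holdout = restricted_holdout, ...)
  sel_local <- ft$levels[[length(ft$levels)]]$selected
  # map back to original column ids
  orig_cols <- which(features$columns$channel %in% chans)[sel_local]
  structure(
    list(channel = ch, feature = ft, selected_channels = chans,
         selected_columns = orig_cols,
         n_evals = ch$n_evals + ft$n_evals),
    class = "mlpso_cf_result"
  )
}

#' @export
print.mlpso_result <- function(x, ...) {
  last <- x$levels[[length(x$levels)]]
  cat(sprintf("<mlpso_result> %s selection, %d level(s); final selection: %d %s(s) (%d fitness evaluations)\n",
              x$granularity, length(x$levels), last$n_selected, x$granularity, x$n_evals))
  invisible(x)
}

#' @export
print.mlpso_cf_result <- function(x, ...) {
  cat(sprintf("<mlpso_cf_result> channel phase -> %d channels; feature phase -> %d features (%d fitness evaluations)\n",
              length(x$selected_channels), length(x$selected_columns), x$n_evals))
  invisible(x)
}

#' Per-level summary of a multilevel selection run
#'
#' @param x An `mlpso_result`.
#' @param ... Unused.
#' @return A tibble with one row per level: `level`, `n_selected`, gbest
#'   `fitness`, `n_evals`, and — when a holdout set was supplied —
#'   `accuracy`, `kappa`, `f_score`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
tidy.mlpso_result <- function(x, ...) {
  purrr::map_dfr(x$levels, function(lv) {
    row <- tibble::tibble(level = lv$level, n_selected = lv$n_selected,
                          fitness = lv$fitness, n_evals = lv$n_evals)
    if (!is.null(lv$report)) {
      row <- dplyr::bind_cols(row, glance.eval_report(lv$report))
    }
    row
  })
}

#' One-row summary of a multilevel selection run
#'
#' @param x An `mlpso_result`.
#' @param ... Unused.
#' @return A tibble: granularity, number of levels, final selection size,
#'   total fitness evaluations, and final holdout accuracy if available.
#' @export
glance.mlpso_result <- function(x, ...) {
  last <- x$levels[[length(x$levels)]]
  tibble::tibble(
    granularity = x$granularity, n_levels = length(x$levels),
    n_selected = last$n_selected, n_evals = x$n_evals,
    accuracy = if (!is.null(last$report)) last$report$accuracy else NA_real_
  )
}

#' Plot selection-size and fitness trajectories across levels
#'
#' @param object An `mlpso_result`.
#' @param ... Unused.
#' @return A ggplot of `n_selected` (and holdout accuracy when available)
#'   by level.
#' @export
autoplot.mlpso_result <- function(object, ...) {
  df <- tidy.mlpso_result(object)
  keep <- intersect(c("n_selected", "accuracy", "fitness"), names(df))
  long <- tidyr::pivot_longer(df[, c("level", keep)], -"level",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "PSO level", y = NULL,
                  title = sprintf("Multilevel %s selection", object$granularity)) +
    ggplot2::theme_minimal()
}

#' Plain-text channel report for a selection run
#'
#' Tabulates, per level, which channels survive — the textual counterpart
#' of an electrode-grid map. For feature-granularity runs the channels are
#' those with at least one selected feature.
#'
#' @param x An `mlpso_result`.
#' @return A tibble with `level`, `n_channels`, and a comma-separated
#'   `channels` string.
#' @export
channel_report <- function(x) {
  stopifnot(inherits(x, "mlpso_result"))
  purrr::map_dfr(x$levels, function(lv) {
    chans <- if (x$granularity == "channel") {
      lv$selected
    } else {
      sort(unique(x$columns$channel[lv$selected]))
    }
    tibble::tibble(level = lv$level, n_channels = length(chans),
                   channels = paste(chans, collapse = ","))
  })
}
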