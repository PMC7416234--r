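#' Write a trial tensor as a plain-text container
#'
#' One tab-separated file per trial (`trial_0001.tsv`, channels as columns,
#' one time sample per row) plus a JSON sidecar `meta.json` holding the
#' sampling rate, channel names and labels. Values are written with 17
#' significant digits, so [read_trials()] reproduces the tensor exactly.
#'
#' @param trials A [trial_tensor()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(trials$data)
  for (i in seq_len(d[1L])) {
    m <- t(trials$data[i, , , drop = TRUE])
    if (d[2L] == 1L) m <- matrix(trials$data[i, 1, ], ncol = 1)
    txt <- apply(matrix(sprintf("%.17g", m), nrow = nrow(m)), 1, paste, collapse = "\t")
    writeLines(c(paste(trials$channel_names, collapse = "\t"), txt),
               file.path(dir, sprintf("trial_%04d.tsv", i)))
  }
  jsonlite::write_json(
    list(fs = trials$fs, n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
         channel_names = trials$channel_names, labels = trials$labels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a trial tensor from its plain-text container
#'
#' @param dir Directory written by [write_trials()].
#' @return A [trial_tensor()].
#' @export
read_trials <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dat <- array(0, dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (i in seq_len(meta$n_trials)) {
    m <- as.matrix(utils::read.delim(file.path(dir, sprintf("trial_%04d.tsv", i)),
                                     check.names = FALSE))
    dat[i, , ] <- t(m)
  }
  trial_tensor(dat, meta$labels, meta$fs, meta$channel_names)
}

#' Write a feature matrix to delimited text
#'
#' Tab-separated, header `ch{c}_f{f}` per feature column, one trial per
#' row, final column `label`. Full-precision values; round-trips exactly
#' through [read_features()].
#'
#' @param features A `feature_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  vals <- matrix(sprintf("%.17g", features$values), nrow = nrow(features$values))
  rows <- apply(cbind(vals, as.character(features$labels)), 1, paste, collapse = "\t")
  writeLines(c(paste(c(colnames(features$values), "label"), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a feature matrix from delimited text
#'
#' Channel and frequency provenance is parsed back from the `ch{c}_f{f}`
#' header names.
#'
#' @param path File written by [write_features()].
#' @param fs Sampling rate to record (metadata only; default `NA`).
#' @param cfg Optional [mst_config()] to attach.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path, fs = NA_real_, cfg = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  labels <- as.integer(tab$label)
  tab$label <- NULL
  vals <- as.matrix(tab)
  mt <- regmatches(colnames(vals), regexec("^ch([0-9]+)_f([0-9.]+)$", colnames(vals)))
  if (any(vapply(mt, length, integer(1)) != 3L)) {
    stop("feature columns must be named ch{channel}_f{frequency}", call. = FALSE)
  }
  channel <- vapply(mt, function(m) as.integer(m[2]), integer(1))
  freq <- vapply(mt, function(m) as.numeric(m[3]), numeric(1))
  columns <- tibble::tibble(column = seq_along(channel), channel = channel,
                            channel_name = paste0("ch", channel), freq_hz = freq)
  new_feature_matrix(vals, columns, labels, fs, cfg)
}

#' Write a selection mask with provenance
#'
#' One row per coordinate of the search space: the 0/1 bit plus its channel
#' (and frequency, at feature granularity).
#'
#' @param result An `mlpso_result` (the final level's mask is written) or a
#'   plain 0/1 vector.
#' @param path Output TSV path.
#' @param columns Column-provenance tibble (required for a plain vector at
#'   feature granularity); ignored for `mlpso_result`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(result, path, columns = NULL) {
  if (inherits(result, "mlpso_result")) {
    last <- result$levels[[length(result$levels)]]
    if (result$granularity == "channel") {
      chans <- sort(unique(result$columns$channel))
      df <- data.frame(channel = chans, bit = as.integer(chans %in% last$selected))
    } else {
      df <- data.frame(column = result$columns$column,
                       channel = result$columns$channel,
                       freq_hz = result$columns$freq_hz,
                       bit = as.integer(result$columns$column %in% last$selected))
    }
  } else {
    bits <- as.integer(result)
    if (!is.null(columns)) {
      df <- data.frame(column = columns$column, channel = columns$channel,
                       freq_hz = columns$freq_hz, bit = bits)
    } else {
      df <- data.frame(column = seq_along(bits), bit = bits)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted Bayesian discriminant to JSON
#'
#' @param model A [blda()] fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_blda <- function(model, path) {
  stopifnot(inherits(model, "blda"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized Bayesian discriminant
#'
#' @param path JSON file written by [write_blda()].
#' @return A [blda()] model usable with [predict.blda()].
#' @export
read_blda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$feature_names <- if (length(obj$feature_names) == 0) NULL else obj$feature_names
  structure(obj, class = "blda")
}

pipeline_defaults <- function() {
  list(
    analysis_fs = 100, p = 0.85, q = 1, f_min = 1, f_max = 35, f_step = 1,
    n_particles = 100, n_iter = 100, c1 = 1.5, c2 = 1.5,
    w_max = 0.8, w_min = 0.4, v_max = 20,
    standardize = TRUE, target_coding = "label",
    scheme = "feature", max_level = 10, seed = 1L,
    split_frac = 0.25, holdout_frac = 0.25,
    fitness_on_holdout = FALSE, use_scores = FALSE, n_folds = 1L
  )
}

#' Assemble a full pipeline configuration
#'
#' Merges user overrides into the default parameter set: analysis rate and
#' MST window (`p = 0.85`, `q = 1`, 1-35 Hz grid), swarm parameters
#' (`N = 100`, `T = 100`, `c1 = c2 = 1.5`, inertia 0.8 -> 0.4,
#' `v_max = 20`), classifier options, the selection scheme and level cap,
#' and the seed/split fractions. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `pipeline_config`.
#' @examples
#' pipeline_config(scheme = "channel", max_level = 4, seed = 7)
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  if (!cfg$scheme %in% c("none", "channel", "feature", "channel-feature")) {
    stop('`scheme` must be one of "none", "channel", "feature", "channel-feature"', call. = FALSE)
  }
  # constructor validation of the component configs
  mst_config(cfg$p, cfg$q, cfg$f_min, cfg$f_max, cfg$f_step)
  pso_config(cfg$n_particles, cfg$n_iter, cfg$c1, cfg$c2, cfg$w_max, cfg$w_min,
             cfg$v_max, cfg$seed)
  if (cfg$max_level < 1) stop("`max_level` must be >= 1", call. = FALSE)
  if (cfg$split_frac <= 0 || cfg$split_frac >= 1) stop("`split_frac` must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`); keys are validated against the
#' known parameter set and unknown keys rejected.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json or .yaml/.yml", call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration file
#'
#' @param cfg A [pipeline_config()].
#' @param path Output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}
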