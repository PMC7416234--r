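#' MST power-spectral-density feature matrix
#'
#' Extracts one non-negative feature per (channel, frequency) pair from
#' every trial: the time-averaged squared magnitude of the modified
#' S-transform voice at that frequency,
#' `feature(ch, f) = mean_tau |S_ch(tau, f)|^2`.
#' Columns are ordered channel-major, frequencies ascending within channel
#' (`ch1_f1, ch1_f2, ..., ch2_f1, ...`), so with the 35-frequency default
#' grid a 64-channel recording yields 2240 features per trial.
#'
#' By Parseval's identity on the S-transform voice, the time-averaged
#' power equals `(1/N^2) sum_m |Y_m G_m|^2` where `Y` is the shifted
#' spectrum and `G` the window transform, so extraction needs a single FFT
#' per channel-signal; equality with the full [modified_stockwell_transform()]
#' map is exercised in the test suite.
#'
#' @param trials A [trial_tensor()] already at the analysis sampling rate.
#' @param cfg An [mst_config()].
#' @return A `feature_matrix`: list with `values` (numeric matrix, trials x
#'   features, named `ch{c}_f{f}`), `columns` (tibble: `column`, `channel`,
#'   `channel_name`, `freq_hz`), `labels`, `fs` and `cfg`.
#' @examples
#' tt <- make_fixture("tiny", seed = 1)
#' fm <- extract_features(tt, mst_config())
#' dim(fm$values)  # 40 x 280 (8 channels x 35 frequencies)
#' @export
extract_features <- function(trials, cfg = mst_config()) {
  stopifnot(inherits(trials, "trial_tensor"), inherits(cfg, "mst_config"))
  fs <- trials$fs
  n <- n_samples(trials)
  freqs <- mst_freqs(cfg)
  if (fs / n > cfg$f_min + 1e-12) {
    stop(sprintf(
      "trial too short to resolve f_min = %g Hz: frequency resolution is fs/n_samples = %g Hz",
      cfg$f_min, fs / n
    ), call. = FALSE)
  }
  if (max(freqs) >= fs / 2) {
    stop("f_max must lie below the Nyquist frequency fs/2", call. = FALSE)
  }
  nf <- length(freqs)
  nch <- n_channels(trials)
  ntr <- n_trials(trials)

  # per-voice squared window transform and circular shift index, precomputed
  nu <- dft_freqs(n, fs)
  Gsq <- sapply(freqs, function(f) exp(-2 * pi^2 * mst_sigma(f, cfg$p, cfg$q)^2 * nu^2)^2)
  k <- freqs * n / fs
  aligned <- all(abs(k - round(k)) < 1e-9)
  if (aligned) {
    shift_idx <- sapply(as.integer(round(k)), function(kk) ((seq_len(n) - 1L + kk) %% n) + 1L)
  }

  vals <- matrix(0, nrow = ntr, ncol = nch * nf)
  for (i in seq_len(ntr)) {
    for (j in seq_len(nch)) {
      x <- trials$data[i, j, ]
      if (aligned) {
        P <- Mod(stats::fft(x))^2
        feat <- colSums(matrix(P[shift_idx], nrow = n) * Gsq) / n^2
      } else {
        X <- stats::fft(x)
        feat <- vapply(seq_len(nf), function(m) {
          v <- st_voice(x, X, fs, freqs[m], mst_sigma(freqs[m], cfg$p, cfg$q))
          mean(Mod(v)^2)
        }, numeric(1))
      }
      vals[i, ((j - 1L) * nf + 1L):(j * nf)] <- feat
    }
  }
  columns <- tibble::tibble(
    column = seq_len(nch * nf),
    channel = rep(seq_len(nch), each = nf),
    channel_name = rep(trials$channel_names, each = nf),
    freq_hz = rep(freqs, times = nch)
  )
  colnames(vals) <- paste0("ch", columns$channel, "_f", columns$freq_hz)
  new_feature_matrix(vals, columns, trials$labels, fs, cfg)
}

new_feature_matrix <- function(values, columns, labels, fs, cfg) {
  stopifnot(nrow(values) == length(labels), ncol(values) == nrow(columns))
  structure(
    list(values = values, columns = columns, labels = as.integer(labels),
         fs = fs, cfg = cfg),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%d channels x %d frequencies)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$columns$channel)), length(unique(x$columns$freq_hz))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Convert a feature matrix to a tibble
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per trial: all feature columns plus a
#'   final `label` column.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  out$label <- x$labels
  out
}

#' Restrict a feature matrix to a set of columns
#'
#' @param features A `feature_matrix`.
#' @param cols Column indices (into the current column order) to keep.
#' @return A `feature_matrix` with re-indexed columns; channel/frequency
#'   provenance is preserved.
#' @export
select_columns <- function(features, cols) {
  stopifnot(inherits(features, "feature_matrix"))
  cols <- sort(unique(as.integer(cols)))
  if (length(cols) < 1L || any(cols < 1L) || any(cols > ncol(features$values))) {
    stop("invalid column selection", call. = FALSE)
  }
  columns <- features$columns[cols, ]
  columns$column <- seq_len(nrow(columns))
  new_feature_matrix(features$values[, cols, drop = FALSE], columns,
                     features$labels, features$fs, features$cfg)
}

#' Restrict a feature matrix to a set of channels
#'
#' Keeps every feature column whose provenance channel is in `channels`
#' (contiguous per-channel blocks of the frequency grid).
#'
#' @param features A `feature_matrix`.
#' @param channels Channel indices to keep.
#' @return A `feature_matrix` restricted to those channels.
#' @export
select_channels <- function(features, channels) {
  stopifnot(inherits(features, "feature_matrix"))
  keep <- which(features$columns$channel %in% channels)
  if (length(keep) < 1L) stop("channel selection matches no feature columns", call. = FALSE)
  select_columns(features, keep)
}

# rows of a feature matrix
subset_rows <- function(features, i) {
  new_feature_matrix(features$values[i, , drop = FALSE], features$columns,
                     features$labels[i], features$fs, features$cfg)
}
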