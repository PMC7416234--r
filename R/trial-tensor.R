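#' Labeled multichannel trial tensor
#'
#' Container for a block of two-class multichannel trials: a 3-D numeric
#' array laid out trials x channels x time samples, a per-trial label vector
#' in \{-1, +1\}, and the sampling rate. This is the raw input of the
#' pipeline; everything downstream (features, reports, traces) is tabular.
#'
#' @param data Numeric 3-D array `[n_trials, n_channels, n_samples]`.
#' @param labels Integer-ish vector of length `n_trials` with values -1/+1.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of channel names; defaults
#'   to `ch1 ... chK`.
#'
#' @return An object of class `trial_tensor`.
#' @examples
#' x <- array(rnorm(4 * 2 * 50), dim = c(4, 2, 50))
#' tt <- trial_tensor(x, c(-1, -1, 1, 1), fs = 50)
#' tt
#' @export
trial_tensor <- function(data, labels, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array [trials x channels x samples]", call. = FALSE)
  }
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  labels <- as.integer(labels)
  if (dim(data)[1L] != length(labels)) {
    stop("length(labels) must equal the number of trials (dim(data)[1])", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(-1L, 1L))) {
    stop("labels must take values -1 and +1 only", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  } else if (length(channel_names) != dim(data)[2L]) {
    stop("channel_names length must equal the number of channels", call. = FALSE)
  }
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_tensor> %d trials x %d channels x %d samples @ %g Hz (%g s)\n",
    d[1], d[2], d[3], x$fs, d[3] / x$fs
  ))
  tab <- table(factor(x$labels, levels = c(-1, 1)))
  cat(sprintf("  labels: %d x -1, %d x +1\n", tab[[1]], tab[[2]]))
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_samples <- function(x) dim(x$data)[3L]

#' Subset trials of a trial tensor
#'
#' @param x A [trial_tensor()].
#' @param i Trial indices to keep.
#' @return A `trial_tensor` with the selected trials.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "trial_tensor"))
  trial_tensor(x$data[i, , , drop = FALSE], x$labels[i], x$fs, x$channel_names)
}

#' Downsample a trial tensor with anti-alias filtering
#'
#' Reduces the sampling rate by an integer factor. Before decimation every
#' channel of every trial is low-pass filtered with a zero-phase (forward
#' and reverse) order-4 Butterworth filter with cutoff at 0.8 times the
#' target Nyquist frequency, so spectral content below the new Nyquist rate
#' is preserved and no group delay is introduced into trial-locked data.
#'
#' @param trials A [trial_tensor()].
#' @param target_fs Target sampling rate in Hz; must divide `trials$fs`
#'   exactly.
#' @return A `trial_tensor` at `target_fs` with unchanged labels.
#' @examples
#' x <- array(rnorm(2 * 1 * 1000), dim = c(2, 1, 1000))
#' tt <- trial_tensor(x, c(-1, 1), fs = 1000)
#' dim(downsample_trials(tt, 100))  # 2 x 1 x 100
#' @export
downsample_trials <- function(trials, target_fs) {
  stopifnot(inherits(trials, "trial_tensor"))
  fs <- trials$fs
  if (target_fs <= 0) stop("`target_fs` must be positive", call. = FALSE)
  if (target_fs == fs) return(trials)
  if (target_fs > fs) stop("`target_fs` exceeds the current sampling rate", call. = FALSE)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf(
      "decimation ratio fs/target_fs = %g is not an integer; resample to a divisor of %g Hz",
      ratio, fs
    ), call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  # cutoff: 0.8 x target Nyquist, normalized to current Nyquist
  bf <- signal::butter(4, 0.8 * target_fs / fs, type = "low")
  d <- dim(trials$data)
  keep <- seq(1L, d[3L], by = ratio)
  out <- array(0, dim = c(d[1L], d[2L], length(keep)))
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      y <- signal::filtfilt(bf, trials$data[i, j, ])
      out[i, j, ] <- y[keep]
    }
  }
  trial_tensor(out, trials$labels, target_fs, trials$channel_names)
}

# stratified split of trial/row indices by label; returns list(train, eval)
stratified_split <- function(labels, eval_frac, seed) {
  stopifnot(eval_frac > 0, eval_frac < 1)
  idx_eval <- integer(0)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    ii <- which(labels == cl)
    k <- max(1L, round(length(ii) * eval_frac))
    idx_eval <- c(idx_eval, sample(ii, k))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  idx_eval <- sort(idx_eval)
  list(train = setdiff(seq_along(labels), idx_eval), eval = idx_eval)
}
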