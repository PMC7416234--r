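#' Modified Stockwell transform configuration
#'
#' Parameters of the frequency-scaled Gaussian analysis window and the
#' integer-Hz frequency grid used for feature extraction. The window
#' standard deviation at frequency `f` is `sigma(f) = p / f^q` seconds; the
#' classical S-transform is `p = q = 1`. Smaller `p` narrows the window in
#' time (better time localisation, coarser frequency resolution). Defaults
#' follow the motor-imagery band: 1-35 Hz in 1-Hz steps with `p = 0.85`,
#' `q = 1`.
#'
#' @param p Window width scale factor (> 0).
#' @param q Window height scale factor (> 0); exponent of the frequency.
#' @param f_min,f_max,f_step Frequency grid in Hz (`0 < f_min <= f_max`,
#'   `f_step > 0`).
#' @return A list of class `mst_config`.
#' @examples
#' mst_config()                # paper-band defaults
#' mst_config(p = 1, q = 1)    # classical S-transform window
#' @export
mst_config <- function(p = 0.85, q = 1, f_min = 1, f_max = 35, f_step = 1) {
  if (!is.numeric(p) || p <= 0) stop("`p` must be > 0", call. = FALSE)
  if (!is.numeric(q) || q <= 0) stop("`q` must be > 0", call. = FALSE)
  if (f_min <= 0 || f_max < f_min) stop("need 0 < f_min <= f_max", call. = FALSE)
  if (f_step <= 0) stop("`f_step` must be > 0", call. = FALSE)
  structure(list(p = p, q = q, f_min = f_min, f_max = f_max, f_step = f_step),
            class = "mst_config")
}

mst_freqs <- function(cfg) seq(cfg$f_min, cfg$f_max, by = cfg$f_step)

#' Gaussian window standard deviation of the modified S-transform
#'
#' @param f Frequency in Hz.
#' @param p,q Scale factors; `p = q = 1` gives the classical `1/f` window.
#' @return Standard deviation in seconds, `p / f^q`.
#' @examples
#' mst_sigma(10, p = 0.85, q = 1)  # 0.085 s
#' @export
mst_sigma <- function(f, p = 1, q = 1) p / f^q

# DFT frequencies of an n-point transform at rate fs, wrapped to +/- fs/2
dft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# One voice of the (modified) S-transform via the frequency-domain
# algorithm: shift the spectrum by f, multiply by the Fourier transform of
# the unit-area Gaussian window, inverse-transform. The signal is treated
# as periodic (the transform is built on the DFT), so this equals the
# direct discretization of the analysis integral with a periodized window.
st_voice <- function(x, X, fs, f, sigma) {
  n <- length(x)
  k <- f * n / fs
  if (abs(k - round(k)) < 1e-9) {
    # f sits on a DFT bin: the shifted spectrum is a circular shift
    Y <- X[((seq_len(n) - 1L + as.integer(round(k))) %% n) + 1L]
  } else {
    Y <- stats::fft(x * exp(-2i * pi * f * (0:(n - 1)) / fs))
  }
  G <- exp(-2 * pi^2 * sigma^2 * dft_freqs(n, fs)^2)
  stats::fft(Y * G, inverse = TRUE) / n
}

st_engine <- function(x, fs, freqs, p, q) {
  if (!is.numeric(x) || length(x) < 2L) stop("`x` must be a numeric vector", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  if (any(freqs <= 0)) {
    stop("frequencies must be strictly positive (the f = 0 voice is the signal mean and is excluded)",
         call. = FALSE)
  }
  n <- length(x)
  X <- stats::fft(x)
  S <- matrix(0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    S[i, ] <- st_voice(x, X, fs, freqs[i], mst_sigma(freqs[i], p, q))
  }
  structure(
    list(values = S, freqs = as.numeric(freqs), times = (0:(n - 1)) / fs, fs = fs,
         p = p, q = q),
    class = "tf_map"
  )
}

#' Stockwell transform of a signal
#'
#' Time-frequency decomposition with a Gaussian window whose standard
#' deviation scales as `1/f`: each output row is the complex S-transform
#' voice `S(tau, f)` sampled at every time point of the input. Implemented
#' with the standard frequency-domain algorithm (one FFT of the signal,
#' spectral shift per voice, multiplication by the Gaussian's transform,
#' inverse FFT), which is `O(N log N)` per frequency.
#'
#' @param x Real numeric signal.
#' @param fs Sampling rate in Hz.
#' @param freqs Strictly positive analysis frequencies in Hz.
#' @return A `tf_map`: complex matrix `values` `[n_freqs x n_times]` plus
#'   `freqs` and `times` vectors.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 0.01)[-101])
#' m <- stockwell_transform(x, fs = 100, freqs = 1:35)
#' m$freqs[which.max(rowMeans(Mod(m$values)))]  # 10
#' @seealso [modified_stockwell_transform()]
#' @export
stockwell_transform <- function(x, fs, freqs) {
  st_engine(x, fs, freqs, p = 1, q = 1)
}

#' Modified Stockwell transform
#'
#' Identical to [stockwell_transform()] except that the Gaussian window
#' standard deviation is `sigma(f) = p / f^q` instead of `1/f`, trading
#' frequency resolution for time localisation (the window keeps its
#' `1/(sigma sqrt(2 pi))` unit-area normalisation). With `p = q = 1` the
#' output equals the classical transform exactly.
#'
#' @param x Real numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cfg An [mst_config()]; supplies `p`, `q` and the frequency grid.
#' @param freqs Optional explicit frequency vector overriding the grid in
#'   `cfg`.
#' @return A `tf_map` (see [stockwell_transform()]).
#' @export
modified_stockwell_transform <- function(x, fs, cfg = mst_config(), freqs = NULL) {
  stopifnot(inherits(cfg, "mst_config"))
  if (is.null(freqs)) freqs <- mst_freqs(cfg)
  st_engine(x, fs, freqs, p = cfg$p, q = cfg$q)
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frequencies (%g-%g Hz) x %d time points @ %g Hz; sigma(f) = %g/f^%g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times), x$fs, x$p, x$q))
  invisible(x)
}

#' Tidy a time-frequency map into a long tibble
#'
#' @param x A `tf_map` from [stockwell_transform()].
#' @param ... Unused.
#' @return A tibble with columns `time`, `freq`, `amplitude` (modulus) and
#'   `power` (squared modulus).
#' @export
tidy.tf_map <- function(x, ...) {
  amp <- Mod(x$values)
  tibble::tibble(
    time = rep(x$times, each = length(x$freqs)),
    freq = rep(x$freqs, times = length(x$times)),
    amplitude = as.vector(amp),
    power = as.vector(amp)^2
  )
}

#' Plot a time-frequency map
#'
#' @param object A `tf_map`.
#' @param ... Unused.
#' @return A ggplot raster of spectral amplitude over time and frequency.
#' @export
autoplot.tf_map <- function(object, ...) {
  df <- tidy.tf_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|S|",
                  title = sprintf("S-transform amplitude (sigma = %g/f^%g)", object$p, object$q)) +
    ggplot2::theme_minimal()
}
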