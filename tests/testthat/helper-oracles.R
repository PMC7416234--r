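# Independent oracles used across the suite. These deliberately avoid the
# package's fast code paths: the S-transform oracle is a direct double loop
# over (tau, t) of the analysis integral with a periodized Gaussian window,
# and the spectrum oracle is a direct DFT sum.

# direct discretization of the S-transform: S(tau, f) =
#   dt * sum_t x(t) g_per(tau - t, f) exp(-2 pi i f t)
# with g_per the Gaussian window (sd sigma = p/f^q, unit area) periodized
# over the record length.
st_direct <- function(x, fs, freqs, p = 1, q = 1, wraps = 12) {
  n <- length(x)
  dt <- 1 / fs
  tt <- (0:(n - 1)) * dt
  span <- n * dt
  out <- matrix(0i, nrow = length(freqs), ncol = n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- p / f^q
    for (l in seq_len(n)) {
      tau <- tt[l]
      g <- 0
      for (k in -wraps:wraps) {
        g <- g + exp(-(tau - tt + k * span)^2 / (2 * sigma^2))
      }
      g <- g / (sigma * sqrt(2 * pi))
      out[fi, l] <- sum(x * g * exp(-2i * pi * f * tt)) * dt
    }
  }
  out
}

# continuous-style Fourier coefficient X(f) = dt * sum_t x(t) e^{-2 pi i f t}
dft_coef <- function(x, fs, f) {
  tt <- (0:(length(x) - 1)) / fs
  sum(x * exp(-2i * pi * f * tt)) / fs
}

# dominant-frequency oracle from the raw periodogram
periodogram_peak <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2))
  ((half - 1) * fs / n)[which.max(p[half])]
}

# brute-force 2x2 confusion by explicit pair counting
confusion_brute <- function(truth, predicted) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && predicted[i] == 1) tp <- tp + 1L
    if (truth[i] == -1 && predicted[i] == -1) tn <- tn + 1L
    if (truth[i] == -1 && predicted[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && predicted[i] == -1) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# band power of a signal from the periodogram, for generator checks
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (0:(n - 1)) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}

# small deterministic two-class feature set with a planted informative
# block, for classifier tests that do not need the signal machinery
toy_features <- function(n_per_class = 30, d = 8, d_info = 3, sep = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * d), ncol = d)
  x[, seq_len(d_info)] <- x[, seq_len(d_info)] + sep * y / 2
  list(x = x, y = y)
}
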