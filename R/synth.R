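#' Synthetic two-class trial generator configuration
#'
#' Parameters of the planted-truth simulator: every channel of every trial
#' carries `1/f^gamma` colored noise; on the informative channels a
#' band-limited oscillatory component is added whose power differs between
#' the two classes by the relative `effect_size` — the band-power
#' (ERD/ERS-like) modulation that motor-imagery features rely on. Defaults
#' emulate a 64-channel, 3-s, 100-Hz recording with 8 informative channels
#' carrying mu (8-12 Hz) and beta (18-26 Hz) band effects.
#'
#' @param n_trials_per_class Trials per class (labels are balanced).
#' @param n_channels Number of channels.
#' @param informative_channels Channel indices carrying the class effect.
#' @param bands List of `c(f_lo, f_hi)` Hz bands (within `(0, fs/2)`).
#' @param effect_size Relative band-power modulation: class +1 power is
#'   scaled by `1 + effect_size` and class -1 by `1 - effect_size` in
#'   odd-numbered bands, and vice versa in even-numbered bands. Must be in
#'   `[0, 1)`; 0 makes the classes statistically identical.
#' @param fs Sampling rate in Hz.
#' @param duration Trial length in seconds.
#' @param noise_exponent Spectral slope `gamma` of the `1/f^gamma` noise.
#' @param osc_amplitude Root-mean-square amplitude scale of the oscillatory
#'   component at `effect_size = 0`, relative to the unit-variance noise
#'   floor. The default 0.05 puts an all-channel classifier of the default
#'   geometry in the high-80s/low-90s accuracy range — the regime of an
#'   unoptimized motor-imagery pipeline — leaving measurable headroom for
#'   selection.
#' @param burst_power If `TRUE` (default) the oscillatory power of each
#'   (trial, channel, band) is additionally multiplied by an independent
#'   unit-mean exponential draw, mimicking the strong trial-to-trial
#'   burstiness of sensorimotor band power (single-trial ERD/ERS is highly
#'   variable). This caps single-channel discriminability, so class
#'   information genuinely has to be pooled across informative channels.
#'   With `FALSE` the oscillation amplitude is deterministic per class.
#' @param seed RNG seed; regeneration is bit-identical.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100, n_channels = 64,
                         informative_channels = 1:8,
                         bands = list(c(8, 12), c(18, 26)),
                         effect_size = 0.8, fs = 100, duration = 3,
                         noise_exponent = 1, osc_amplitude = 0.05,
                         burst_power = TRUE, seed = 1L) {
  if (length(informative_channels) > 0 &&
      (any(informative_channels < 1) || any(informative_channels > n_channels))) {
    stop("informative_channels must lie in [1, n_channels]", call. = FALSE)
  }
  if (effect_size < 0 || effect_size >= 1) stop("`effect_size` must be in [0, 1)", call. = FALSE)
  if (effect_size > 0 && length(informative_channels) == 0) {
    stop("nonzero effect_size requires a nonempty informative channel set", call. = FALSE)
  }
  for (b in bands) {
    if (length(b) != 2 || b[1] <= 0 || b[2] >= fs / 2 || b[1] >= b[2]) {
      stop("each band must be c(f_lo, f_hi) with 0 < f_lo < f_hi < fs/2", call. = FALSE)
    }
  }
  ns <- fs * duration
  if (abs(ns - round(ns)) > 1e-9) stop("fs * duration must be an integer sample count", call. = FALSE)
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels),
         informative_channels = as.integer(informative_channels),
         bands = bands, effect_size = effect_size, fs = fs, duration = duration,
         noise_exponent = noise_exponent, osc_amplitude = osc_amplitude,
         burst_power = isTRUE(burst_power), seed = as.integer(seed)),
    class = "synth_config"
  )
}

# one segment of 1/f^gamma noise via spectral shaping: Hermitian spectrum
# with magnitude f^(-gamma/2) and random phases, normalized to unit sd
colored_noise <- function(n, fs, gamma) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  mag <- f^(-gamma / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  half <- mag * exp(1i * phase)
  spec <- complex(n)
  spec[2:(nf + 1)] <- half
  if (n %% 2 == 0) {
    spec[nf + 1] <- Re(spec[nf + 1])  # Nyquist bin real
    if (nf > 1) spec[n:(nf + 2)] <- Conj(half[1:(nf - 1)])
  } else {
    spec[n:(nf + 2)] <- Conj(half[1:nf])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-15) return(rep(0, n)) else x / s
}

# band-limited oscillation: white noise through a zero-phase order-4
# Butterworth band-pass, unit sd
band_noise <- function(n, fs, lo, hi) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  # generate extra samples and trim so filter edge transients stay out
  pad <- min(n, 200L)
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x / stats::sd(x)
}

#' Generate synthetic two-class multichannel trials
#'
#' Draws a balanced, label-shuffled set of trials under a [synth_config()]:
#' colored `1/f^gamma` noise everywhere, plus class-modulated band-limited
#' oscillations on the informative channels. The oscillatory component of
#' band `b` on an informative channel has power
#' `osc_amplitude^2 * (1 +/- effect_size)` in expectation, the sign
#' depending on class and band parity, so class band-power ratios are
#' `(1 + effect)/(1 - effect)`; with `burst_power` (the default) the
#' realised power of every (trial, channel, band) fluctuates around that
#' mean with an independent unit-mean exponential draw.
#'
#' @param cfg A [synth_config()].
#' @return A list with `trials` (a [trial_tensor()]) and `truth`, a
#'   manifest recording the planted ground truth (informative channels,
#'   bands, per-band class sign convention, effect size, seed).
#' @examples
#' sim <- simulate_trials(synth_config(n_trials_per_class = 5, n_channels = 4,
#'                                     informative_channels = 1:2, duration = 1))
#' sim$trials
#' sim$truth$informative_channels
#' @export
simulate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$fs * cfg$duration))
  ntr <- 2L * cfg$n_trials_per_class
  labels <- sample(rep(c(-1L, 1L), cfg$n_trials_per_class))
  dat <- array(0, dim = c(ntr, cfg$n_channels, n))
  info <- cfg$informative_channels
  for (i in seq_len(ntr)) {
    for (j in seq_len(cfg$n_channels)) {
      x <- colored_noise(n, cfg$fs, cfg$noise_exponent)
      if (j %in% info) {
        for (b in seq_along(cfg$bands)) {
          band_sign <- if (b %% 2 == 1) 1 else -1
          pw <- 1 + band_sign * labels[i] * cfg$effect_size
          if (cfg$burst_power) pw <- pw * stats::rexp(1)
          x <- x + cfg$osc_amplitude * sqrt(pw) *
            band_noise(n, cfg$fs, cfg$bands[[b]][1], cfg$bands[[b]][2])
        }
      }
      dat[i, j, ] <- x
    }
  }
  truth <- list(
    informative_channels = info, bands = cfg$bands,
    band_class_sign = ifelse(seq_along(cfg$bands) %% 2 == 1, 1, -1),
    effect_size = cfg$effect_size, noise_exponent = cfg$noise_exponent,
    osc_amplitude = cfg$osc_amplitude, burst_power = cfg$burst_power,
    seed = cfg$seed
  )
  list(trials = trial_tensor(dat, labels, cfg$fs), truth = truth)
}

#' Ready-made synthetic fixtures
#'
#' Canned simulator presets used throughout the documentation and tests:
#' \describe{
#'   \item{`"tiny"`}{40 trials x 8 channels x 1 s at 100 Hz, 2 informative
#'     channels with strong fixed-amplitude oscillations (no power bursts),
#'     so classes are cleanly separable — a fast, deterministic fixture for
#'     unit tests. Returns a [trial_tensor()].}
#'   \item{`"competition-shape"`}{The competition-dataset geometry: 278 training
#'     and 100 test trials x 64 channels x 3 s at 100 Hz, 8 informative
#'     channels. Returns `list(train, test)` of trial tensors.}
#'   \item{`"selection"`}{The selection-study preset: 200 trials (150
#'     train + 50 test) x 32 channels x 3 s at 100 Hz, 8 informative
#'     channels, effect size 0.8. Returns `list(train, test, truth)`.}
#' }
#'
#' @param kind One of `"tiny"`, `"competition-shape"`, `"selection"`.
#' @param seed RNG seed.
#' @param effect_size Band-power modulation; default 0.8.
#' @return See above.
#' @export
make_fixture <- function(kind = c("tiny", "competition-shape", "selection"),
                         seed = 1L, effect_size = 0.8) {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    cfg <- synth_config(n_trials_per_class = 20, n_channels = 8,
                        informative_channels = c(2L, 5L),
                        effect_size = effect_size, fs = 100, duration = 1,
                        osc_amplitude = 0.3, burst_power = FALSE, seed = seed)
    return(simulate_trials(cfg)$trials)
  }
  if (kind == "competition-shape") {
    cfg_tr <- synth_config(n_trials_per_class = 139, n_channels = 64,
                           informative_channels = 1:8,
                           effect_size = effect_size, fs = 100, duration = 3,
                           seed = seed)
    cfg_te <- cfg_tr
    cfg_te$n_trials_per_class <- 50L
    cfg_te$seed <- seed + 100000L
    return(list(train = simulate_trials(cfg_tr)$trials,
                test = simulate_trials(cfg_te)$trials))
  }
  cfg_tr <- synth_config(n_trials_per_class = 75, n_channels = 32,
                         informative_channels = seq(3, 31, by = 4),
                         effect_size = effect_size, fs = 100, duration = 3,
                         seed = seed)
  cfg_te <- cfg_tr
  cfg_te$n_trials_per_class <- 25L
  cfg_te$seed <- seed + 100000L
  tr <- simulate_trials(cfg_tr)
  te <- simulate_trials(cfg_te)
  list(train = tr$trials, test = te$trials, truth = tr$truth)
}
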