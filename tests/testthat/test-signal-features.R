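test_that("downsampling decimates exactly, keeps labels, and preserves in-band content", {
  set.seed(11)
  dat <- array(rnorm(2 * 2 * 3000), dim = c(2, 2, 3000))
  tt <- trial_tensor(dat, c(-1, 1), fs = 1000)

  out <- downsample_trials(tt, 100)
  expect_equal(dim(out$data), c(2, 2, 300))
  expect_identical(out$labels, tt$labels)
  expect_equal(out$fs, 100)

  # identity case
  expect_identical(downsample_trials(tt, 1000), tt)

  # non-integer ratio rejected
  expect_error(downsample_trials(tt, 300), "not an integer")

  # a pure 5 Hz tone survives: dominant DFT bin unchanged (direct DFT oracle)
  tone <- sin(2 * pi * 5 * (0:2999) / 1000)
  tt5 <- trial_tensor(array(tone, dim = c(1, 1, 3000)), 1, fs = 1000)
  expect_equal(periodogram_peak(tone, 1000), 5)
  out5 <- downsample_trials(tt5, 100)
  expect_equal(periodogram_peak(out5$data[1, 1, ], 100), 5)
})

test_that("S-transform localises a sinusoid at its frequency and vanishes on zero input", {
  fs <- 100
  n <- 200
  for (f0 in c(7, 13, 25)) {
    x <- cos(2 * pi * f0 * (0:(n - 1)) / fs)
    m <- stockwell_transform(x, fs, 1:35)
    expect_equal(m$freqs[which.max(rowMeans(Mod(m$values)))], f0)
  }
  z <- stockwell_transform(rep(0, n), fs, 1:35)
  expect_true(all(Mod(z$values) == 0))
  expect_error(stockwell_transform(rnorm(64), fs, 0:5), "positive")
})

test_that("fast S-transform matches the direct double-loop discretization", {
  set.seed(5)
  fs <- 32
  x <- rnorm(64)
  freqs <- c(1, 2, 3, 5, 8)
  fast <- stockwell_transform(x, fs, freqs)$values
  direct <- st_direct(x, fs, freqs, p = 1, q = 1)
  expect_lt(max(Mod(fast - direct)) / max(Mod(direct)), 1e-6)

  # and for the modified window
  fast_m <- modified_stockwell_transform(x, fs, mst_config(p = 0.85, q = 1, f_min = 1, f_max = 8),
                                         freqs = freqs)$values
  direct_m <- st_direct(x, fs, freqs, p = 0.85, q = 1)
  expect_lt(max(Mod(fast_m - direct_m)) / max(Mod(direct_m)), 1e-6)
})

test_that("time-marginal of the S-transform recovers the Fourier spectrum", {
  set.seed(6)
  fs <- 100
  n <- 200
  x <- rnorm(n) + sin(2 * pi * 9 * (0:(n - 1)) / fs)
  for (pq in list(c(1, 1), c(0.85, 1))) {
    m <- modified_stockwell_transform(x, fs, mst_config(p = pq[1], q = pq[2]))
    for (f in c(3, 9, 20, 34)) {
      xf <- dft_coef(x, fs, f)
      marg <- sum(m$values[match(f, m$freqs), ]) / fs
      expect_lt(Mod(marg - xf) / Mod(xf), 1e-3)
    }
  }
})

test_that("modified transform generalises the classical one", {
  set.seed(7)
  # p = q = 1 reduces to the classical transform bit for bit
  for (rep in 1:3) {
    x <- rnorm(256)
    a <- stockwell_transform(x, 128, 1:20)$values
    b <- modified_stockwell_transform(x, 128, mst_config(p = 1, q = 1, f_max = 20))$values
    expect_lt(max(Mod(a - b)), 1e-8)
  }

  # window standard deviation follows p / f^q
  expect_equal(mst_sigma(10, p = 0.85, q = 1), 0.085)
  expect_error(mst_config(p = 0), "> 0")
  expect_error(mst_config(q = -1), "> 0")

  # smaller p narrows the |S| ridge in time: for an impulse the voice
  # magnitude is exactly the Gaussian window, so the rms time-width of the
  # ridge equals sigma = p/f
  fs <- 100
  x <- rep(0, 300); x[150] <- 1
  ridge_width <- function(p, f) {
    m <- modified_stockwell_transform(x, fs, mst_config(p = p, q = 1), freqs = f)
    a <- Mod(m$values[1, ])
    tt <- m$times
    sqrt(sum(a * (tt - tt[which.max(a)])^2) / sum(a))
  }
  for (f in c(10, 25)) {
    expect_lt(ridge_width(0.85, f), ridge_width(1, f))
    expect_equal(ridge_width(0.85, f), 0.85 / f, tolerance = 0.02)
  }
})

test_that("PSD features count channels x frequencies, localise tones, and are non-negative", {
  # 64 channels x 35 integer frequencies -> 2240 columns
  set.seed(8)
  dat <- array(rnorm(2 * 64 * 100), dim = c(2, 64, 100))
  fm64 <- extract_features(trial_tensor(dat, c(-1, 1), fs = 100))
  expect_equal(ncol(fm64$values), 2240)
  expect_equal(fm64$columns$channel[36], 2L)  # channel-major order
  expect_equal(fm64$columns$freq_hz[1:3], c(1, 2, 3))

  # a single-channel 10 Hz tone peaks at (ch, 10 Hz); periodogram oracle agrees
  tone <- sin(2 * pi * 10 * (0:199) / 100)
  dat1 <- array(tone, dim = c(1, 1, 200))
  fm <- extract_features(trial_tensor(dat1, 1, fs = 100))
  expect_equal(fm$columns$freq_hz[which.max(fm$values[1, ])], 10)
  expect_equal(periodogram_peak(tone, 100), 10)

  # zero trial -> all-zero row; everything non-negative
  dat2 <- array(0, dim = c(1, 2, 100))
  fm0 <- extract_features(trial_tensor(dat2, -1, fs = 100))
  expect_true(all(fm0$values == 0))

  # property: non-negativity and column-count identity across random shapes
  for (i in 1:5) {
    set.seed(100 + i)
    nch <- sample(1:5, 1)
    fmr <- extract_features(
      trial_tensor(array(rnorm(3 * nch * 100), dim = c(3, nch, 100)),
                   c(-1, 1, -1), fs = 100),
      mst_config(f_max = 20)
    )
    expect_equal(ncol(fmr$values), nch * 20)
    expect_true(all(fmr$values >= 0))
  }

  # features equal the time-averaged squared magnitude of the full map
  set.seed(9)
  x <- rnorm(100)
  fm1 <- extract_features(trial_tensor(array(x, dim = c(1, 1, 100)), 1, fs = 100))
  map <- modified_stockwell_transform(x, 100, mst_config())
  expect_equal(fm1$values[1, ], rowMeans(Mod(map$values)^2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # too-short trials are rejected
  expect_error(
    extract_features(trial_tensor(array(rnorm(50), dim = c(1, 1, 50)), 1, fs = 100)),
    "resolve"
  )
})

test_that("channel and column restriction preserve provenance", {
  tt <- make_fixture("tiny", seed = 1)
  fm <- extract_features(tt)
  one_ch <- select_channels(fm, 3)
  expect_equal(ncol(one_ch$values), 35)
  expect_true(all(one_ch$columns$channel == 3))
  sub <- select_columns(fm, c(5, 40, 100))
  expect_equal(sub$columns$freq_hz, fm$columns$freq_hz[c(5, 40, 100)])
  expect_error(select_channels(fm, 99), "no feature columns")
})
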