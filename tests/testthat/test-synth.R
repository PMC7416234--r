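test_that("generated tensors have the configured shape, balance and determinism", {
  cfg <- synth_config(n_trials_per_class = 5, n_channels = 4,
                      informative_channels = 1:2, fs = 100, duration = 1, seed = 3)
  sim <- simulate_trials(cfg)
  expect_equal(dim(sim$trials$data), c(10, 4, 100))
  expect_equal(sum(sim$trials$labels == 1), 5)
  expect_equal(sim$truth$informative_channels, 1:2)

  # fixed seed -> bit-identical tensor
  sim2 <- simulate_trials(cfg)
  expect_identical(sim$trials$data, sim2$trials$data)
  cfg_b <- cfg; cfg_b$seed <- 4L
  expect_false(identical(simulate_trials(cfg_b)$trials$data, sim$trials$data))

  # invalid configurations are rejected
  expect_error(synth_config(informative_channels = 99, n_channels = 8), "n_channels")
  expect_error(synth_config(informative_channels = integer(0), effect_size = 0.5),
               "nonempty informative")
  expect_error(synth_config(bands = list(c(10, 60))), "fs/2")
})

test_that("fixtures have their documented geometry", {
  tiny <- make_fixture("tiny", seed = 1)
  expect_equal(dim(tiny$data), c(40, 8, 100))
  expect_equal(tiny$fs, 100)

  ps <- make_fixture("competition-shape", seed = 1, effect_size = 0.8)
  expect_equal(dim(ps$train$data), c(278, 64, 300))
  expect_equal(dim(ps$test$data), c(100, 64, 300))

  t1 <- make_fixture("tiny", seed = 1)
  t2 <- make_fixture("tiny", seed = 2)
  expect_equal(dim(t1$data), dim(t2$data))
  expect_false(identical(t1$data, t2$data))
})

test_that("planted band-power effects land on the informative channels", {
  # detection-oriented conditions: fixed-amplitude oscillations; the bursty
  # default regime is exercised by the study-preset recovery suite
  cfg <- synth_config(n_trials_per_class = 30, n_channels = 8,
                      informative_channels = c(2, 5), effect_size = 0.8,
                      fs = 100, duration = 1, osc_amplitude = 0.3,
                      burst_power = FALSE, seed = 7)
  sim <- simulate_trials(cfg)
  tt <- sim$trials
  # band powers computed directly from the raw signals (periodogram oracle)
  tstat <- sapply(1:8, function(ch) {
    bp <- apply(tt$data[, ch, ], 1, band_power, fs = 100, lo = 8, hi = 12)
    abs(t.test(bp[tt$labels == 1], bp[tt$labels == -1])$statistic)
  })
  expect_true(all(sort(order(tstat, decreasing = TRUE)[1:2]) == c(2, 5)))

  # MST feature recoverability: informative columns separate the classes,
  # noise channels survive a Bonferroni screen
  hits <- 0L
  for (s in 1:5) {
    cfg$seed <- s + 100L
    sim_s <- simulate_trials(cfg)
    fm <- extract_features(sim_s$trials)
    pvals <- apply(fm$values, 2, function(col) {
      if (sd(col) == 0) return(1)
      t.test(col[fm$labels == 1], col[fm$labels == -1])$p.value
    })
    info_cols <- fm$columns$channel %in% c(2, 5)
    ok_signal <- min(pvals[info_cols]) < 1e-3
    ok_null <- all(pvals[!info_cols] >= 1e-3 / ncol(fm$values))
    hits <- hits + as.integer(ok_signal && ok_null)
  }
  expect_gte(hits, 4L)
})

test_that("the noise floor has the configured 1/f^gamma spectral slope", {
  for (gamma in c(0.5, 1, 1.5)) {
    cfg <- synth_config(n_trials_per_class = 20, n_channels = 2,
                        informative_channels = integer(0), effect_size = 0,
                        noise_exponent = gamma, fs = 100, duration = 2, seed = 11)
    sim <- simulate_trials(cfg)
    n <- 200
    pxx <- matrix(0, nrow = 40, ncol = 0)
    f <- (1:99) * 100 / n
    keep <- f >= 2 & f <= 40
    avg <- rep(0, sum(keep))
    for (i in 1:40) {
      for (ch in 1:2) {
        p <- (Mod(stats::fft(sim$trials$data[i, ch, ]))^2 / n)[2:100]
        avg <- avg + p[keep]
      }
    }
    slope <- coef(lm(log(avg) ~ log(f[keep])))[2]
    expect_lt(abs(slope - (-gamma)), 0.3)
  }
})

test_that("zero effect size makes the two classes statistically identical", {
  cfg <- synth_config(n_trials_per_class = 25, n_channels = 4,
                      informative_channels = 1:2, effect_size = 0,
                      fs = 100, duration = 1, seed = 13)
  sim <- simulate_trials(cfg)
  fm <- extract_features(sim$trials)
  pvals <- apply(fm$values, 2, function(col) {
    t.test(col[fm$labels == 1], col[fm$labels == -1])$p.value
  })
  # no column should survive a Bonferroni screen
  expect_true(all(pvals > 0.05 / length(pvals)))
})
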