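# small helpers shared by the multilevel tests
tiny_features <- function(seed = 51) {
  extract_features(make_fixture("tiny", seed = seed))
}
fast_cfg <- function(seed = 1, N = 12, T = 10) {
  pso_config(n_particles = N, n_iter = T, seed = seed)
}

test_that("levels are nested, shrink the search space, and always halt", {
  fm <- tiny_features()
  ml <- run_multilevel(fm, "feature", fast_cfg(seed = 2), max_level = 4)
  expect_lte(length(ml$levels), 4)
  sels <- lapply(ml$levels, `[[`, "selected")
  for (k in seq_along(sels)[-1]) {
    expect_true(all(sels[[k]] %in% sels[[k - 1]]))
  }
  # per-level gbest traces are monotone
  for (lv in ml$levels) {
    expect_true(all(diff(lv$trace$gbest_fitness) >= 0))
  }
})

test_that("termination fires when consecutive levels select equal counts", {
  fm <- tiny_features()
  ml <- run_multilevel(fm, "channel", fast_cfg(seed = 3, N = 16, T = 12), max_level = 8)
  counts <- vapply(ml$levels, `[[`, integer(1), "n_selected")
  if (length(ml$levels) < 8) {
    n <- length(counts)
    expect_equal(counts[n], counts[n - 1])
  }
  # counts never repeat before the final pair
  if (length(counts) > 2) {
    expect_true(all(counts[seq_len(length(counts) - 2) + 1] != counts[seq_len(length(counts) - 2)]))
  }
})

test_that("max_level = 1 reduces to a single PSO run", {
  fm <- tiny_features()
  cfg <- fast_cfg(seed = 4)
  ml <- run_multilevel(fm, "feature", cfg, max_level = 1)
  expect_equal(length(ml$levels), 1)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L  # level-1 seed derivation
  single <- run_bpso(ncol(fm$values),
                     selection_fitness(fm, "feature", seed = cfg$seed), cfg1)
  expect_identical(sort(ml$levels[[1]]$selected), sort(which(single$mask == 1L)))
})

test_that("channel granularity expands each channel to its frequency block", {
  fm <- tiny_features()
  # dimension of the swarm equals the channel count
  ml <- run_multilevel(fm, "channel", fast_cfg(seed = 5), max_level = 1)
  expect_lte(max(ml$levels[[1]]$selected), 8)
  # one selected channel activates exactly 35 feature columns
  one <- select_channels(fm, 2)
  expect_equal(ncol(one$values), 35)
  # 64-channel input gives a 64-dimensional particle space
  dat <- array(rnorm(8 * 64 * 100), dim = c(8, 64, 100))
  fm64 <- extract_features(trial_tensor(dat, rep(c(-1, 1), 4), fs = 100))
  expect_equal(length(unique(fm64$columns$channel)), 64)
  expect_equal(ncol(fm64$values), 2240)
})

test_that("channel-then-feature restricts the feature space to surviving channels", {
  fm <- tiny_features(seed = 52)
  holdout <- tiny_features(seed = 53)
  cf <- channel_then_feature(fm, fast_cfg(seed = 6), fast_cfg(seed = 7),
                             max_level_channel = 2, max_level_feature = 2,
                             holdout = holdout)
  n_ch <- length(cf$selected_channels)
  # phase 2 starts from exactly 35 columns per surviving channel
  expect_equal(length(unique(cf$feature$columns$channel)), n_ch)
  first_level_dim <- nrow(cf$feature$columns)
  expect_equal(first_level_dim, 35 * n_ch)
  # final columns map into the surviving channels
  expect_true(all(fm$columns$channel[cf$selected_columns] %in% cf$selected_channels))
  # reports were computed on the holdout at every level
  expect_s3_class(cf$channel$levels[[1]]$report, "eval_report")
})

test_that("level summaries, channel reports and plots are well-formed", {
  fm <- tiny_features(seed = 54)
  holdout <- tiny_features(seed = 55)
  ml <- run_multilevel(fm, "channel", fast_cfg(seed = 8), max_level = 3,
                       holdout = holdout)
  td <- tidy(ml)
  expect_true(all(c("level", "n_selected", "fitness", "accuracy") %in% names(td)))
  expect_equal(nrow(td), length(ml$levels))
  cr <- channel_report(ml)
  expect_equal(cr$n_channels[nrow(cr)], glance(ml)$n_selected)
  p <- autoplot(ml)
  expect_s3_class(p, "ggplot")
})

test_that("the fitness-on-holdout switch scores fitness on the supplied evaluation set", {
  fm <- tiny_features(seed = 56)
  holdout <- tiny_features(seed = 57)
  expect_error(run_multilevel(fm, "channel", fast_cfg(seed = 9), max_level = 1,
                              fitness_on_holdout = TRUE),
               "requires an explicit")
  ml <- run_multilevel(fm, "channel", fast_cfg(seed = 9), max_level = 1,
                       holdout = holdout, fitness_on_holdout = TRUE)
  expect_equal(length(ml$levels), 1)
  # when fitness is scored on the holdout, a capped-fitness mask
  # classifies that holdout perfectly
  if (ml$levels[[1]]$fitness >= 1e12) {
    expect_equal(ml$levels[[1]]$report$accuracy, 1)
  }
})
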