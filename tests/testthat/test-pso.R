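test_that("swarm initialization is binary, bounded and seed-reproducible", {
  cfg <- pso_config(seed = 31)
  s1 <- initialize_swarm(2240, cfg)
  expect_equal(dim(s1$x), c(100, 2240))
  expect_true(all(s1$x %in% c(0L, 1L)))
  expect_true(all(abs(s1$v) <= cfg$v_max))
  s2 <- initialize_swarm(2240, cfg)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$v, s2$v)

  # gbest of a fitness-evaluated swarm is the fittest initial particle
  tiny <- pso_config(n_particles = 2, n_iter = 5, seed = 32)
  s3 <- initialize_swarm(1, tiny, fitness = function(m) sum(m))
  expect_true(all(s3$x %in% c(0L, 1L)))
  expect_equal(s3$gbest_fit, max(s3$pbest_fit))
  expect_error(initialize_swarm(0, cfg), ">= 1")
})

test_that("the inertia weight decreases linearly from w_max to w_min", {
  cfg <- pso_config()
  expect_equal(inertia_weight(0, cfg), 0.8)
  expect_equal(inertia_weight(100, cfg), 0.4)
  expect_equal(inertia_weight(50, cfg), 0.6)
  expect_error(inertia_weight(-1, cfg), "0 <= t")
})

test_that("velocity updates respect stagnation and boundary absorption", {
  cfg <- pso_config(n_particles = 4, seed = 33)
  s <- initialize_swarm(6, cfg, fitness = function(m) sum(m))
  # stagnation: x = pbest = gbest and v = 0 stays at rest
  s$pbest_x <- s$x
  s$gbest_x <- s$x[1, ]
  s$x <- matrix(s$gbest_x, 4, 6, byrow = TRUE)
  s$pbest_x <- s$x
  s$v <- matrix(0, 4, 6)
  s2 <- update_velocity(s, cfg, w = 0.8)
  expect_true(all(s2$v == 0))

  # w = 1, c1 = c2 -> 0 leaves in-bound velocities unchanged
  cfg0 <- pso_config(n_particles = 4, c1 = 1e-12, c2 = 1e-12, seed = 33)
  s$v <- matrix(runif(24, -5, 5), 4, 6)
  s3 <- update_velocity(s, cfg0, w = 1)
  expect_equal(s3$v, s$v, tolerance = 1e-9)

  # velocities never escape +/- v_max over many random updates
  set.seed(34)
  s$v <- matrix(runif(24, -19, 19), 4, 6)
  for (i in 1:50) {
    s$pbest_x <- matrix(rbinom(24, 1, 0.5), 4, 6)
    s$gbest_x <- rbinom(6, 1, 0.5)
    s <- update_velocity(s, cfg, w = 0.8)
    expect_true(all(abs(s$v) <= 20))
    s <- update_position(s)
    expect_true(all(s$x %in% c(0L, 1L)))
  }
})

test_that("the sigmoid position rule sets bits with probability s(v)", {
  cfg <- pso_config(n_particles = 1000, seed = 35)
  draw_freq <- function(v, reps = 100) {
    s <- initialize_swarm(100, cfg)
    hits <- 0L
    set.seed(36)
    for (r in seq_len(reps)) {
      s$v <- matrix(v, 1000, 100)
      s <- update_position(s)
      hits <- hits + sum(s$x)
    }
    hits / (reps * 1000 * 100)
  }
  # 1e5+ seeded draws per velocity level
  expect_equal(draw_freq(0, reps = 2), 0.5, tolerance = 0.01)
  expect_equal(draw_freq(1, reps = 2), plogis(1), tolerance = 0.01)
  expect_gte(draw_freq(20, reps = 1), 0.999)

  # chi-square goodness of fit at v = 1 over 1e5 draws
  set.seed(37)
  s <- initialize_swarm(100, cfg)
  s$v <- matrix(1, 1000, 100)
  s <- update_position(s)
  ones <- sum(s$x)
  n <- length(s$x)
  p <- plogis(1)
  chisq <- (ones - n * p)^2 / (n * p) + ((n - ones) - n * (1 - p))^2 / (n * (1 - p))
  expect_lt(chisq, qchisq(0.999, df = 1))
})

test_that("inverse-MSE fitness follows the +/-1 error arithmetic", {
  expect_equal(mse_inverse_fitness(c(1, -1, 1), c(1, -1, 1)), 1e12)
  expect_equal(mse_inverse_fitness(c(1, -1, 1), c(1, 1, 1)), 0.25, tolerance = 1e-10)
  # brute-force enumeration: k errors under +/-1 coding give SSE 4k
  truth <- rep(c(1, -1), 10)
  for (k in 0:5) {
    pred <- truth
    if (k > 0) pred[seq_len(k)] <- -pred[seq_len(k)]
    expect_equal(sum((pred - truth)^2), 4 * k)
    if (k > 0) expect_equal(mse_inverse_fitness(truth, pred), 1 / (4 * k), tolerance = 1e-10)
  }
  expect_error(mse_inverse_fitness(c(1, -1), c(1, -1, 1)), "length mismatch")
})

test_that("the optimizer solves OneMax and planted-mask problems and keeps its invariants", {
  cfg <- pso_config(n_particles = 30, n_iter = 40, seed = 0)
  onemax_hits <- 0L
  for (s in 1:5) {
    cfg$seed <- s
    res <- run_bpso(10, function(m) sum(m), cfg)
    onemax_hits <- onemax_hits + as.integer(res$popcount == 10L)
    expect_true(all(diff(res$trace$gbest_fitness) >= 0))
  }
  expect_gte(onemax_hits, 4L)

  set.seed(38)
  target <- rbinom(15, 1, 0.5); target[1] <- 1L
  cfg$seed <- 99
  res <- run_bpso(15, function(m) 15 - sum(m != target), cfg)
  expect_equal(res$mask, as.integer(target))

  # constant fitness: trace flat at the initial best, ties shrink popcount
  cfg$seed <- 5
  resc <- run_bpso(8, function(m) 1, cfg)
  expect_true(all(resc$trace$gbest_fitness == 1))
  expect_true(all(diff(resc$trace$gbest_popcount) <= 0))

  # full reproducibility of the trajectory
  r1 <- run_bpso(12, function(m) sum(m * (1:12)), pso_config(n_particles = 10, n_iter = 10, seed = 77))
  r2 <- run_bpso(12, function(m) sum(m * (1:12)), pso_config(n_particles = 10, n_iter = 10, seed = 77))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)

  # non-finite fitness aborts with a diagnostic
  expect_error(run_bpso(4, function(m) NaN, pso_config(n_particles = 4, n_iter = 2, seed = 1)),
               "non-finite")
})

test_that("the wrapper fitness scores masks by held-out classifier error", {
  tt <- make_fixture("tiny", seed = 41)
  fm <- extract_features(tt)
  # the continuous (raw-score) criterion resolves the ranking even when
  # thresholded labels tie on a small split
  fit_s <- selection_fitness(fm, "channel", seed = 41, use_scores = TRUE)
  info <- c(2L, 5L)
  mask_info <- as.integer(seq_len(8) %in% info)
  mask_noise <- as.integer(seq_len(8) %in% c(1L, 4L))
  expect_gt(fit_s(mask_info), fit_s(mask_noise))

  # thresholded default: perfect label prediction hits the capped maximum
  fit_l <- selection_fitness(fm, "channel", seed = 41)
  expect_lte(fit_l(mask_info), 1e12)
  expect_identical(fit_l(rep(0L, 8)), -Inf)

  # config invariants
  expect_error(pso_config(n_particles = 1), ">= 2")
  expect_error(pso_config(v_max = 0), "> 0")
  expect_error(pso_config(w_max = 0.2, w_min = 0.4), "w_max >= w_min")
})
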