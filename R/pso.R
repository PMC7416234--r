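#' Binary PSO configuration
#'
#' Swarm parameters for the sigmoid-transfer binary particle swarm
#' optimizer. Defaults are the tuned values for wrapper selection on
#' motor-imagery PSD features: 100 particles, 100 iterations,
#' `c1 = c2 = 1.5`, inertia decreasing linearly from 0.8 to 0.4, and
#' velocities clamped to +/- 20 (boundary absorption).
#'
#' @param n_particles Swarm size `N` (>= 2).
#' @param n_iter Maximum iterations `T` (>= 1).
#' @param c1,c2 Cognitive / social acceleration coefficients (> 0).
#' @param w_max,w_min Inertia-weight bounds (`w_max >= w_min > 0`).
#' @param v_max Velocity bound (> 0).
#' @param seed RNG seed; the full trajectory is a deterministic function of
#'   `(seed, config, fitness)`.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 100, n_iter = 100, c1 = 1.5, c2 = 1.5,
                       w_max = 0.8, w_min = 0.4, v_max = 20, seed = 1L) {
  if (n_particles < 2) stop("`n_particles` must be >= 2", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("`c1` and `c2` must be > 0", call. = FALSE)
  if (!(w_max >= w_min && w_min > 0)) stop("need w_max >= w_min > 0", call. = FALSE)
  if (v_max <= 0) stop("`v_max` must be > 0", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles), n_iter = as.integer(n_iter),
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min, v_max = v_max,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Linearly decreasing inertia weight
#'
#' `w(t) = w_max - (w_max - w_min) * t / T`: large early inertia favours
#' exploration, small late inertia favours exploitation.
#'
#' @param t Current iteration, `0 <= t <= T`.
#' @param cfg A [pso_config()].
#' @return The inertia weight at iteration `t`.
#' @examples
#' inertia_weight(0, pso_config())    # 0.8
#' inertia_weight(100, pso_config())  # 0.4
#' @export
inertia_weight <- function(t, cfg) {
  stopifnot(inherits(cfg, "pso_config"))
  if (any(t < 0) || any(t > cfg$n_iter)) stop("need 0 <= t <= T", call. = FALSE)
  cfg$w_max - (cfg$w_max - cfg$w_min) * t / cfg$n_iter
}

# fitness of each row-mask of a binary matrix; all-zero masks score -Inf
# without calling the fitness (an empty selection is never a valid model)
eval_positions <- function(x, fitness) {
  pop <- rowSums(x)
  fit <- rep(-Inf, nrow(x))
  for (i in which(pop > 0)) {
    fi <- fitness(x[i, ])
    if (is.na(fi) || is.nan(fi) || fi == Inf) {
      stop("fitness function returned a non-finite value for a nonempty mask", call. = FALSE)
    }
    fit[i] <- fi
  }
  list(fit = fit, pop = pop, n_evals = sum(pop > 0))
}

# TRUE where candidate (fit, popcount) beats incumbent; ties on fitness are
# broken toward fewer selected bits (preference for smaller subsets)
beats <- function(fit, pop, inc_fit, inc_pop) {
  fit > inc_fit | (fit == inc_fit & pop < inc_pop)
}

update_best <- function(state) {
  imp <- beats(state$fit, state$pop, state$pbest_fit, state$pbest_pop)
  state$pbest_x[imp, ] <- state$x[imp, , drop = FALSE]
  state$pbest_fit[imp] <- state$fit[imp]
  state$pbest_pop[imp] <- state$pop[imp]
  # gbest: scan pbest in particle order so equal candidates resolve to the
  # lowest index
  for (i in seq_len(nrow(state$x))) {
    if (beats(state$pbest_fit[i], state$pbest_pop[i], state$gbest_fit, state$gbest_pop)) {
      state$gbest_x <- state$pbest_x[i, ]
      state$gbest_fit <- state$pbest_fit[i]
      state$gbest_pop <- state$pbest_pop[i]
    }
  }
  state
}

#' Initialize a binary particle swarm
#'
#' Positions are independent Bernoulli(0.5) bits, velocities uniform on
#' `[-v_max, v_max]`; personal bests are the initial positions and the
#' global best is the fittest initial particle. Seeds the RNG from
#' `cfg$seed`, so the same seed reproduces the swarm bit for bit.
#'
#' @param d Mask dimension (>= 1).
#' @param cfg A [pso_config()].
#' @param fitness Fitness function: binary vector of length `d` -> finite
#'   scalar, higher is better. If omitted, best-so-far fields start at
#'   `-Inf` fitness.
#' @return A `swarm_state` list: `x`, `v`, `pbest_*`, `gbest_*`, iteration
#'   counter `t` and evaluation counter `n_evals`.
#' @export
initialize_swarm <- function(d, cfg = pso_config(), fitness = NULL) {
  stopifnot(inherits(cfg, "pso_config"))
  if (d < 1) stop("mask dimension `d` must be >= 1", call. = FALSE)
  set.seed(cfg$seed)
  N <- cfg$n_particles
  x <- matrix(as.integer(stats::runif(N * d) < 0.5), nrow = N, ncol = d)
  v <- matrix(stats::runif(N * d, -cfg$v_max, cfg$v_max), nrow = N, ncol = d)
  state <- list(
    x = x, v = v,
    pbest_x = x, pbest_fit = rep(-Inf, N), pbest_pop = rowSums(x),
    gbest_x = x[1, ], gbest_fit = -Inf, gbest_pop = sum(x[1, ]),
    fit = rep(-Inf, N), pop = rowSums(x),
    t = 0L, n_evals = 0L
  )
  class(state) <- "swarm_state"
  if (!is.null(fitness)) {
    ev <- eval_positions(x, fitness)
    state$fit <- ev$fit; state$pop <- ev$pop; state$n_evals <- ev$n_evals
    state$pbest_fit <- ev$fit; state$pbest_pop <- ev$pop
    state <- update_best(state)
  }
  state
}

#' Velocity update with boundary absorption
#'
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh
#' `r1, r2 ~ U(0, 1)` per particle and dimension; any component beyond
#' `+/- v_max` is clamped to the boundary.
#'
#' @param state A `swarm_state`.
#' @param cfg A [pso_config()].
#' @param w Inertia weight for this iteration (see [inertia_weight()]).
#' @return The state with updated velocities.
#' @export
update_velocity <- function(state, cfg, w) {
  N <- nrow(state$x); d <- ncol(state$x)
  r1 <- matrix(stats::runif(N * d), N, d)
  r2 <- matrix(stats::runif(N * d), N, d)
  g <- matrix(state$gbest_x, N, d, byrow = TRUE)
  v <- w * state$v + cfg$c1 * r1 * (state$pbest_x - state$x) + cfg$c2 * r2 * (g - state$x)
  state$v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  state
}

#' Sigmoid position update of binary PSO
#'
#' Each bit is redrawn as 1 with probability `s(v)` (logistic sigmoid of
#' its velocity): `x <- 1 if r < s(v) else 0`, `r ~ U(0, 1)`.
#'
#' @param state A `swarm_state` whose velocities were just updated.
#' @return The state with redrawn binary positions.
#' @export
update_position <- function(state) {
  N <- nrow(state$x); d <- ncol(state$x)
  r <- matrix(stats::runif(N * d), N, d)
  state$x <- matrix(as.integer(r < stats::plogis(state$v)), N, d)
  state
}

#' Run the binary particle swarm optimizer
#'
#' Maximises `fitness` over binary masks of length `d`. One iteration is
#' synchronous: all velocities are updated from the previous iteration's
#' global best, then all positions are redrawn through the sigmoid rule,
#' then all fitnesses are evaluated, then personal/global bests are
#' refreshed. Ties on fitness resolve toward masks with fewer set bits,
#' then toward the lower particle index. The global-best fitness trace is
#' non-decreasing by construction.
#'
#' @param d Mask dimension.
#' @param fitness Function: binary vector of length `d` -> finite scalar
#'   (higher is better). All-zero masks are scored `-Inf` internally and
#'   never become a best position.
#' @param cfg A [pso_config()]; `cfg$seed` fixes the whole trajectory.
#' @return An object of class `bpso_result`: `mask` (0/1 integer vector),
#'   `fitness`, `popcount`, `trace` (tibble: `iteration`, `gbest_fitness`,
#'   `gbest_popcount`), `n_evals` and the config.
#' @examples
#' res <- run_bpso(10, fitness = sum, cfg = pso_config(n_particles = 20, n_iter = 30, seed = 7))
#' res$mask  # all ones: the OneMax optimum
#' @export
run_bpso <- function(d, fitness, cfg = pso_config()) {
  stopifnot(inherits(cfg, "pso_config"), is.function(fitness))
  state <- initialize_swarm(d, cfg, fitness)
  trace <- matrix(0, nrow = cfg$n_iter + 1L, ncol = 3L)
  trace[1L, ] <- c(0, state$gbest_fit, state$gbest_pop)
  for (t in seq_len(cfg$n_iter)) {
    w <- inertia_weight(t, cfg)
    state <- update_velocity(state, cfg, w)
    state <- update_position(state)
    ev <- eval_positions(state$x, fitness)
    state$fit <- ev$fit; state$pop <- ev$pop
    state$n_evals <- state$n_evals + ev$n_evals
    state <- update_best(state)
    state$t <- t
    trace[t + 1L, ] <- c(t, state$gbest_fit, state$gbest_pop)
  }
  structure(
    list(mask = as.integer(state$gbest_x), fitness = state$gbest_fit,
         popcount = state$gbest_pop,
         trace = tibble::tibble(iteration = trace[, 1], gbest_fitness = trace[, 2],
                                gbest_popcount = trace[, 3]),
         n_evals = state$n_evals, config = cfg),
    class = "bpso_result"
  )
}

#' @export
print.bpso_result <- function(x, ...) {
  cat(sprintf("<bpso_result> d = %d, %d/%d bits set, gbest fitness = %.6g (%d evaluations)\n",
              length(x$mask), x$popcount, length(x$mask), x$fitness, x$n_evals))
  invisible(x)
}

#' Plot the global-best fitness trace of a PSO run
#'
#' @param object A `bpso_result`.
#' @param ... Unused.
#' @return A ggplot line chart of gbest fitness and popcount by iteration.
#' @export
autoplot.bpso_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"iteration",
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL, title = "Binary PSO global best") +
    ggplot2::theme_minimal()
}

#' Inverse-MSE fitness of thresholded predictions
#'
#' The wrapper fitness: the reciprocal of the summed squared error between
#' predicted and true -1/+1 labels, `1 / (sum (yhat - y)^2 + eps)`. Under
#' +/-1 coding each misclassification contributes 4, so one error on any
#' evaluation set gives fitness ~0.25, two errors ~0.125, and a perfect
#' prediction the capped maximum `1/eps`.
#'
#' @param truth True labels (-1/+1 or real targets).
#' @param predicted Predicted labels/targets of the same length.
#' @param eps Small constant keeping the fitness finite at zero error.
#' @return A positive scalar fitness (higher is better).
#' @examples
#' mse_inverse_fitness(c(1, -1, 1), c(1, 1, 1))  # one error: 0.25
#' @export
mse_inverse_fitness <- function(truth, predicted, eps = 1e-12) {
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  1 / (sum((predicted - truth)^2) + eps)
}

#' Build a wrapper-selection fitness around the Bayesian discriminant
#'
#' Returns a closure `mask -> fitness` for [run_bpso()]: the classifier is
#' fitted on the training rows restricted to the columns the mask selects,
#' predictions are made on the evaluation rows, and the inverse-MSE of the
#' thresholded -1/+1 labels (or raw scores, if `use_scores = TRUE`) is
#' returned.
#'
#' By default the evaluation rows are a seeded stratified validation split
#' carved out of `features` itself, so no held-out test labels influence
#' the selection. Supplying `eval_features` instead scores masks on that
#' explicit set (the protocol in which selection fitness is computed on the
#' test data itself; use only to reproduce that design).
#'
#' @param features Training `feature_matrix`.
#' @param granularity `"feature"` (mask bits index feature columns) or
#'   `"channel"` (mask bits index channels; a set channel activates its
#'   whole per-channel block of frequency columns).
#' @param active Indices (columns or channels, per `granularity`) that the
#'   mask positions refer to; defaults to all.
#' @param eval_features Optional explicit evaluation `feature_matrix`.
#' @param split_frac Fraction of training trials held out as the internal
#'   validation split when `eval_features` is `NULL` and `n_folds = 1`.
#' @param seed Seed of the internal validation split / fold assignment.
#' @param use_scores Score masks on raw discriminant outputs rather than
#'   thresholded labels. The score criterion is continuous, so it resolves
#'   the marginal contribution of a coordinate even when the discrete error
#'   count on the split ties.
#' @param n_folds With `n_folds > 1` the fitness is cross-validated: the
#'   training trials are partitioned into `n_folds` seeded stratified folds
#'   and the squared errors of the held-out predictions of every fold are
#'   pooled, so each mask is judged on all training trials rather than one
#'   small split. Default 1 (single `split_frac` validation split).
#' @param eps See [mse_inverse_fitness()].
#' @return A function taking a 0/1 mask and returning a scalar fitness.
#'   Degenerate fits (e.g. a single-class training split) score `-Inf`.
#' @export
selection_fitness <- function(features, granularity = c("feature", "channel"),
                              active = NULL, eval_features = NULL,
                              split_frac = 0.25, seed = 1L,
                              use_scores = FALSE, n_folds = 1L, eps = 1e-12) {
  stopifnot(inherits(features, "feature_matrix"))
  granularity <- match.arg(granularity)
  if (is.null(active)) {
    active <- if (granularity == "channel") {
      sort(unique(features$columns$channel))
    } else {
      seq_len(ncol(features$values))
    }
  }
  if (!is.null(eval_features)) {
    stopifnot(inherits(eval_features, "feature_matrix"))
    folds <- list(list(x_tr = features$values, y_tr = features$labels,
                       x_ev = eval_features$values, y_ev = eval_features$labels))
  } else if (n_folds > 1L) {
    assign_fold <- local({
      old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
      set.seed(seed)
      fa <- integer(length(features$labels))
      for (cl in c(-1L, 1L)) {
        ii <- which(features$labels == cl)
        fa[ii] <- sample(rep_len(seq_len(n_folds), length(ii)))
      }
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      fa
    })
    folds <- lapply(seq_len(n_folds), function(k) {
      tr <- assign_fold != k
      list(x_tr = features$values[tr, , drop = FALSE], y_tr = features$labels[tr],
           x_ev = features$values[!tr, , drop = FALSE], y_ev = features$labels[!tr])
    })
  } else {
    sp <- stratified_split(features$labels, split_frac, seed)
    folds <- list(list(x_tr = features$values[sp$train, , drop = FALSE],
                       y_tr = features$labels[sp$train],
                       x_ev = features$values[sp$eval, , drop = FALSE],
                       y_ev = features$labels[sp$eval]))
  }
  chan_of_col <- features$columns$channel

  function(mask) {
    sel <- active[mask == 1L]
    cols <- if (granularity == "channel") which(chan_of_col %in% sel) else sel
    if (length(cols) < 1L) return(-Inf)
    sse <- 0
    for (fd in folds) {
      fit <- tryCatch(blda(fd$x_tr[, cols, drop = FALSE], fd$y_tr),
                      error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      pr <- predict(fit, fd$x_ev[, cols, drop = FALSE])
      yhat <- if (use_scores) pr$score else pr$label
      sse <- sse + sum((yhat - fd$y_ev)^2)
    }
    1 / (sse + eps)
  }
}
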