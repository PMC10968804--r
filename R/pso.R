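# Particle swarm optimization of the (t1, t2) staging thresholds.

#' PSO configuration
#'
#' Defaults follow the training setup used for threshold search: 200
#' particles, 40 iterations, cognitive and social coefficients
#' `c1 = c2 = 1`, and an inertia weight redrawn uniformly from `U(0, 1)`
#' at every iteration (shared across the swarm). The default search box
#' spans the plausible threshold range, `t1` in `[0, 1e-4]` and `t2` in
#' `[0, 1e-3]`; velocities are clamped to a fraction of each dimension's
#' range to prevent divergence.
#'
#' @param swarm_size number of particles (>= 2).
#' @param iterations number of update iterations (>= 1).
#' @param c1,c2 acceleration coefficients.
#' @param bounds 2-column matrix (`lo`, `hi`) with one row per dimension;
#'   row names name the dimensions.
#' @param velocity_clamp maximum speed as a fraction of each range.
#' @param inertia `NULL` for the random-uniform inertia schedule, or a
#'   fixed numeric weight.
#' @param seed RNG seed for reproducible runs, or `NULL`.
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 200L, iterations = 40L, c1 = 1, c2 = 1,
                       bounds = cbind(lo = c(t1 = 0, t2 = 0),
                                      hi = c(t1 = 1e-4, t2 = 1e-3)),
                       velocity_clamp = 0.2, inertia = NULL, seed = NULL) {
  if (!is_count(swarm_size, 2L)) stop("'swarm_size' must be >= 2")
  if (!is_count(iterations, 1L)) stop("'iterations' must be >= 1")
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
    stop("'bounds' must be a matrix with columns lo < hi")
  if (!is.null(inertia) && !is_number(inertia))
    stop("'inertia' must be NULL (random schedule) or a single number")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), c1 = c1, c2 = c2,
                 bounds = bounds, velocity_clamp = velocity_clamp,
                 inertia = inertia, seed = seed),
            class = "pso_config")
}

#' Global-best particle swarm optimization
#'
#' Maximizes `fitness` over the box in `cfg$bounds` with the velocity
#' update `v <- w*v + c1*r1*(p_i - x) + c2*r2*(p_g - x); x <- x + v`,
#' where `r1`, `r2` are drawn fresh per particle and dimension each
#' iteration and the inertia weight `w` is redrawn per iteration (or held
#' fixed if `cfg$inertia` is numeric). Positions are clamped to the box
#' and velocities to `velocity_clamp` times each range. Personal and
#' global bests update only on strict improvement, so ties keep the
#' first-found optimum and runs are deterministic given the seed.
#'
#' @param fitness function mapping a numeric position vector to a single
#'   finite number (larger is better).
#' @param cfg a [pso_config()].
#' @return an object of class `pso_result`: list with `best_position`
#'   (named), `best_fitness`, `history` (global best after each
#'   iteration, non-decreasing), and `seed`.
#' @export
pso_optimize <- function(fitness, cfg = pso_config()) {
  stopifnot(is.function(fitness), inherits(cfg, "pso_config"))
  d <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1L]; hi <- cfg$bounds[, 2L]
  range <- hi - lo
  vmax <- cfg$velocity_clamp * range
  eval_at <- function(x) {
    f <- fitness(x)
    if (!is_number(f))
      stop("non-finite fitness at position (",
           paste(signif(x, 6), collapse = ", "), ")")
    f
  }
  with_seed(cfg$seed, {
    n <- cfg$swarm_size
    X <- t(lo + t(matrix(stats::runif(n * d), n, d)) * range)
    V <- t(t(matrix(stats::runif(n * d), n, d)) * 2 * vmax - vmax)
    fit <- apply(X, 1L, eval_at)
    P <- X; pfit <- fit
    g <- which.max(pfit)
    gbest <- P[g, ]; gfit <- pfit[g]
    history <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      w <- if (is.null(cfg$inertia)) stats::runif(1L) else cfg$inertia
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      V <- w * V + cfg$c1 * r1 * (P - X) +
        cfg$c2 * r2 * (matrix(gbest, n, d, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, n, d, byrow = TRUE)),
                matrix(vmax, n, d, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lo, n, d, byrow = TRUE)),
                matrix(hi, n, d, byrow = TRUE))
      fit <- apply(X, 1L, eval_at)
      better <- fit > pfit
      P[better, ] <- X[better, , drop = FALSE]
      pfit[better] <- fit[better]
      g <- which.max(pfit)
      if (pfit[g] > gfit) {
        gbest <- P[g, ]; gfit <- pfit[g]
      }
      history[it] <- gfit
    }
    names(gbest) <- rownames(cfg$bounds)
    structure(list(best_position = gbest, best_fitness = gfit,
                   history = history, seed = cfg$seed),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> best fitness %.6f at (%s) after %d iterations\n",
              x$best_fitness,
              paste(names(x$best_position), "=",
                    signif(x$best_position, 4), collapse = ", "),
              length(x$history)))
  invisible(x)
}

#' Pooled staging accuracy as a PSO fitness
#'
#' Stages every training night at the candidate thresholds and returns
#' the fraction of epochs agreeing with the technician, pooled over all
#' nights. This is the reference (uncached) fitness; [train_thresholds()]
#' uses an algebraically identical cached version that re-stages from
#' precomputed feature summaries.
#'
#' @param position numeric vector `c(t1, t2)`.
#' @param training list of nights, each a list with elements `features`
#'   (a [feature_series()]) and `truth` (a [hypnogram]).
#' @param tm movement threshold used while staging.
#' @return pooled accuracy in `[0, 1]`.
#' @export
fitness_accuracy <- function(position, training, tm = 5e-4) {
  if (length(training) == 0L) stop("empty training set")
  th <- thresholds(t1 = position[[1L]], t2 = position[[2L]], tm = tm)
  correct <- 0L; total <- 0L
  for (night in training) {
    pred <- stage_night(night$features, th)
    truth <- as_3class(night$truth)
    if (length(truth) != length(pred))
      stop("night has ", length(truth), " technician epochs but ",
           length(pred), " feature epochs")
    correct <- correct + sum(pred$labels == truth$labels)
    total <- total + length(pred)
  }
  correct / total
}

# Precompute per-night staging components once so each PSO evaluation is a
# vector comparison rather than a full re-extraction.
make_cached_fitness <- function(training, tm) {
  if (length(training) == 0L) stop("empty training set")
  cache <- lapply(training, function(night) {
    f <- night$features
    truth <- as_3class(night$truth)
    if (length(truth) != f$n_epochs)
      stop("night has ", length(truth), " technician epochs but ",
           f$n_epochs, " feature epochs")
    list(movement = detect_movement_epochs(movement_flags(f$pm, tm)),
         pw_mat = epoch_matrix(f$pw),
         p80 = apply(epoch_matrix(f$pn3), 2L, percentile_value, p = 80),
         truth = truth$labels)
  })
  total <- sum(vapply(cache, function(x) length(x$truth), integer(1)))
  function(position) {
    t1 <- position[[1L]]; t2 <- position[[2L]]
    correct <- 0L
    for (x in cache) {
      stages <- stage_from_components(x$movement, colSums(x$pw_mat > t1),
                                      x$p80, t1, t2)
      correct <- correct + sum(stages == x$truth)
    }
    correct / total
  }
}
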