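# Hybrid binary/continuous particle swarm optimization over the 28-dimensional
# space (14 feature-mask bits + 14 decision thresholds), in synchronous and
# random-asynchronous update modes.

#' Per-feature threshold search ranges
#'
#' Search ranges are assigned by feature category: amplitude thresholds
#' th1–th5 in \[0, 30\], width thresholds th6–th10 in \[0, 781.25\] and slope
#' thresholds th11–th14 in \[0, 24.16\]. `literal_table = TRUE` reproduces the
#' historically printed dimension-index mapping instead, which splits the
#' categories mid-way (th6–th12 share the width range and only th13–th14 get
#' the slope range) — physically incoherent, but available for comparison.
#'
#' @param literal_table Use the printed index-based mapping.
#' @return A 14x2 matrix with columns `lo`, `hi`.
#' @export
threshold_ranges <- function(literal_table = FALSE) {
  r <- matrix(0, 14L, 2L, dimnames = list(FEATURE_NAMES, c("lo", "hi")))
  if (literal_table) {
    r[1:5, 2L] <- 30
    r[6:12, 2L] <- 781.25
    r[13:14, 2L] <- 24.16
  } else {
    r[AMPLITUDE_FEATURES, 2L] <- 30
    r[WIDTH_FEATURES, 2L] <- 781.25
    r[SLOPE_FEATURES, 2L] <- 24.16
  }
  r
}

#' Swarm configuration
#'
#' Defaults follow the standard wrapper-selection setup: 30 particles, 1000
#' iterations, cognitive and social coefficients `c1 = c2 = 2`, inertia weight
#' decreased linearly from 0.9 to 0.4, binary velocity clamp 6. The continuous
#' velocity clamp is not part of the classical setup and defaults to 20% of
#' each threshold's range width, which keeps wide-range dimensions (widths,
#' range 781.25) from permanently overshooting.
#'
#' @param n_particles Swarm size.
#' @param k_max Number of movement iterations. Evaluation happens `k_max + 1`
#'   times (once for the initial population); `k_max = 0` scores the initial
#'   population only.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param w_max,w_min Inertia weight schedule endpoints.
#' @param v_max_binary Velocity clamp for the 14 mask dimensions.
#' @param v_max_continuous Length-14 clamp for the threshold dimensions, or
#'   `NULL` for 0.2 x range width.
#' @param ranges 14x2 threshold range matrix, see [threshold_ranges()].
#' @param per_dimension_r Draw `r1`, `r2` per dimension instead of the
#'   classical per-particle scalars.
#' @param algorithm `"synchronous"` (standard PSO) or `"random_asynchronous"`
#'   (RA-PSO).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30L, k_max = 1000L, c1 = 2, c2 = 2,
                         w_max = 0.9, w_min = 0.4, v_max_binary = 6,
                         v_max_continuous = NULL,
                         ranges = threshold_ranges(),
                         per_dimension_r = FALSE,
                         algorithm = c("synchronous", "random_asynchronous"),
                         seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_particles >= 1L, k_max >= 0L, w_min > 0, w_min <= w_max,
            nrow(ranges) == 14L, all(ranges[, 2L] >= ranges[, 1L]))
  if (is.null(v_max_continuous)) {
    v_max_continuous <- 0.2 * (ranges[, 2L] - ranges[, 1L])
  }
  stopifnot(length(v_max_continuous) == 14L)
  structure(list(n_particles = as.integer(n_particles),
                 k_max = as.integer(k_max), c1 = c1, c2 = c2,
                 w_max = w_max, w_min = w_min,
                 v_max_binary = v_max_binary,
                 v_max_continuous = as.numeric(v_max_continuous),
                 ranges = ranges, per_dimension_r = per_dimension_r,
                 algorithm = algorithm, seed = seed),
            class = "swarm_config")
}

#' Linearly decreasing inertia weight
#'
#' `w(k) = w_max - ((w_max - w_min) / k_max) * k`, so `w(0) = w_max` and
#' `w(k_max) = w_min`.
#'
#' @param k Iteration counter in `[0, k_max]`.
#' @param cfg A [swarm_config()] (only `w_max`, `w_min`, `k_max` are used).
#' @return The inertia weight.
#' @export
inertia <- function(k, cfg) {
  if (cfg$k_max == 0L) return(cfg$w_max)
  cfg$w_max - (cfg$w_max - cfg$w_min) / cfg$k_max * k
}

#' V-shaped transfer function
#'
#' Maps a velocity to a bit-flip probability: `T(v) = |tanh(v)|`, an even
#' function with `T(0) = 0` and range \[0, 1).
#'
#' @param v Velocity (vectorized).
#' @return Flip probability in \[0, 1).
#' @export
vshape_transfer <- function(v) abs(tanh(v))

#' One velocity update
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, componentwise, then
#' clamped to `[-v_max, v_max]` per dimension.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param w Inertia weight.
#' @param r1,r2 Uniform random numbers in \[0, 1\] (scalars or per-dimension).
#' @param c1,c2 Acceleration coefficients.
#' @param v_max Per-dimension clamp (recycled).
#' @return The new velocity vector.
#' @export
velocity_update <- function(velocity, position, pbest, gbest, w, r1, r2,
                            c1 = 2, c2 = 2, v_max = Inf) {
  v <- w * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Continuous position update with range clipping
#' @param x Current position (vectorized).
#' @param v Velocity.
#' @param lo,hi Range bounds (recycled).
#' @return `x + v` clipped into `[lo, hi]`.
#' @export
position_update_continuous <- function(x, v, lo, hi) {
  pmin(pmax(x + v, lo), hi)
}

#' Binary position update via the v-shaped transfer
#'
#' The bit is complemented when `u < T(v)` and kept otherwise; at `v = 0` the
#' transfer is 0, so the bit can never flip.
#'
#' @param bit Current bit(s) in \{0, 1\}.
#' @param v Velocity.
#' @param u Uniform random number(s) in \[0, 1).
#' @return Updated bit(s).
#' @export
position_update_binary <- function(bit, v, u) {
  ifelse(u < vshape_transfer(v), 1 - bit, bit)
}

# Default fitness factory: decode a particle into a rule model, classify the
# training rows, return the Gmean. `tF` is the transposed feature matrix
# (14 x n), precomputed once.
make_rule_fitness <- function(features, labels, literal_gmean = FALSE) {
  stopifnot(ncol(features) == 14L, nrow(features) == length(labels))
  tF <- t(features)
  labels <- as.logical(labels)
  npos <- sum(labels)
  nneg <- sum(!labels)
  function(mask, thresholds) {
    sel <- which(mask)
    pred <- if (length(sel) == 0L) rep(TRUE, length(labels)) else
      colSums(tF[sel, , drop = FALSE] >= thresholds[sel]) == length(sel)
    tp <- sum(pred & labels)
    tn <- sum(!pred) - (npos - tp)
    tpr <- if (npos == 0L) 0 else tp / npos
    tnr <- if (nneg == 0L) 0 else tn / nneg
    if (literal_gmean) tpr * tnr else sqrt(tpr * tnr)
  }
}

#' Run the particle swarm optimizer
#'
#' Jointly searches the 14-bit feature mask (binary dimensions, moved through
#' the v-shaped transfer) and the 14 decision thresholds (continuous
#' dimensions, moved additively with range clipping), maximizing the Gmean of
#' the decoded rule on the training rows.
#'
#' Initialization: mask bits equiprobable, thresholds uniform in range,
#' velocities zero, pbest/gbest scores 0 (a "not yet evaluated" sentinel
#' consistent with a fitness in \[0, 1\]; gbest replacement is strict, ties
#' keep the incumbent). The initial population is evaluated before the first
#' movement step, after which each of the `k_max` iterations evaluates the
#' whole population once — synchronously (all evaluations, then all moves) or
#' random-asynchronously (particles drawn uniformly with replacement; each
#' drawn particle is evaluated, updates pbest/gbest immediately, and moves
#' immediately using the current gbest, so some particles may move several
#' times per iteration and others not at all).
#'
#' @param features Numeric training matrix with 14 columns.
#' @param labels Logical labels along the rows (from [label_candidates()]).
#' @param cfg A [swarm_config()].
#' @param fixed_mask Optional integer vector of feature indices: freezes the
#'   mask to exactly this subset and optimizes thresholds only (the
#'   fixed-peak-model protocol). Binary dimensions then never move.
#' @param fitness Optional replacement fitness `function(mask, thresholds)`
#'   returning a value in \[0, 1\] (used by the optimizer sanity tests);
#'   `NULL` uses the rule-classifier Gmean on `features`/`labels`.
#' @param literal_gmean Score with the plain `TPR * TNR` product.
#' @return A list of class `swarm_result`: `model` (decoded gbest as a
#'   [rule_model()]), `gbest_score`, `gbest_history` (length `k_max + 1`,
#'   non-decreasing), `evaluations`, and the `config`.
#' @export
run_swarm <- function(features, labels, cfg = swarm_config(),
                      fixed_mask = NULL, fitness = NULL,
                      literal_gmean = FALSE) {
  stopifnot(inherits(cfg, "swarm_config"))
  if (is.null(fitness)) {
    if (is.null(dim(features)) || nrow(features) == 0L) {
      stop("empty training set", call. = FALSE)
    }
    fitness <- make_rule_fitness(features, labels, literal_gmean)
  }
  if (!is.null(cfg$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(as.integer(cfg$seed))
  }

  np <- cfg$n_particles
  lo <- cfg$ranges[, 1L]; hi <- cfg$ranges[, 2L]
  frozen <- !is.null(fixed_mask)
  if (frozen) {
    fmask <- logical(14L); fmask[as.integer(fixed_mask)] <- TRUE
    bits <- matrix(rep(as.numeric(fmask), each = np), np, 14L)
  } else {
    bits <- matrix(as.numeric(stats::runif(np * 14L) < 0.5), np, 14L)
  }
  cont <- matrix(stats::runif(np * 14L, rep(lo, each = np),
                              rep(hi, each = np)), np, 14L)
  vel <- matrix(0, np, 28L)
  v_max <- c(rep(cfg$v_max_binary, 14L), cfg$v_max_continuous)

  pbest_bits <- bits; pbest_cont <- cont
  pbest_score <- rep(0, np)          # sentinel: nothing evaluated yet
  gbest_score <- 0
  gbest_bits <- bits[1L, ]; gbest_cont <- cont[1L, ]
  history <- numeric(cfg$k_max + 1L)
  evals <- 0L

  eval_one <- function(i) {
    evals <<- evals + 1L
    fitness(bits[i, ] > 0.5, cont[i, ])
  }
  absorb <- function(i, score) {
    # strict improvement only; ties keep the incumbent (determinism)
    if (score > pbest_score[i]) {
      pbest_score[i] <<- score
      pbest_bits[i, ] <<- bits[i, ]
      pbest_cont[i, ] <<- cont[i, ]
    }
    if (score > gbest_score) {
      gbest_score <<- score
      gbest_bits <<- bits[i, ]
      gbest_cont <<- cont[i, ]
    }
  }
  move_one <- function(i, w) {
    nr <- if (cfg$per_dimension_r) 28L else 1L
    r1 <- stats::runif(nr); r2 <- stats::runif(nr)
    x <- c(bits[i, ], cont[i, ])
    pb <- c(pbest_bits[i, ], pbest_cont[i, ])
    gb <- c(gbest_bits, gbest_cont)
    v <- velocity_update(vel[i, ], x, pb, gb, w, r1, r2, cfg$c1, cfg$c2,
                         v_max)
    if (frozen) v[1:14] <- 0
    vel[i, ] <<- v
    cont[i, ] <<- position_update_continuous(cont[i, ], v[15:28], lo, hi)
    if (!frozen) {
      u <- stats::runif(14L)
      bits[i, ] <<- position_update_binary(bits[i, ], v[1:14], u)
    }
  }

  # initial synchronous evaluation pass seeds pbest/gbest for both modes
  for (i in seq_len(np)) absorb(i, eval_one(i))
  history[1L] <- gbest_score

  if (cfg$k_max >= 1L) {
    for (k in seq_len(cfg$k_max)) {
      w <- inertia(k - 1L, cfg)
      if (cfg$algorithm == "synchronous") {
        for (i in seq_len(np)) move_one(i, w)
        scores <- vapply(seq_len(np), eval_one, numeric(1L))
        for (i in seq_len(np)) absorb(i, scores[i])
      } else {
        draws <- sample.int(np, np, replace = TRUE)
        for (i in draws) {
          absorb(i, eval_one(i))
          move_one(i, w)
        }
      }
      history[k + 1L] <- gbest_score
    }
  }

  structure(list(model = rule_model(gbest_bits > 0.5, gbest_cont),
                 gbest_score = gbest_score, gbest_history = history,
                 evaluations = evals, config = cfg,
                 fixed_mask = if (frozen) which(fmask) else NULL),
            class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result> %s, %d evaluations, gbest fitness %.5f\n",
              x$config$algorithm, x$evaluations, x$gbest_score))
  print(x$model)
  invisible(x)
}

#' Standard (synchronous) PSO
#'
#' Convenience wrapper: all particles are evaluated, then all pbest/gbest are
#' refreshed, then all particles move.
#'
#' @inheritParams run_swarm
#' @return See [run_swarm()].
#' @export
run_standard_pso <- function(features, labels, cfg = swarm_config(),
                             fixed_mask = NULL, ...) {
  cfg$algorithm <- "synchronous"
  run_swarm(features, labels, cfg, fixed_mask = fixed_mask, ...)
}

#' Random-asynchronous PSO (RA-PSO)
#'
#' Convenience wrapper: per iteration, `n_particles` indices are drawn
#' uniformly with replacement and each drawn particle evaluates, refreshes
#' the shared bests, and moves immediately.
#'
#' @inheritParams run_swarm
#' @return See [run_swarm()].
#' @export
run_rapso <- function(features, labels, cfg = swarm_config(),
                      fixed_mask = NULL, ...) {
  cfg$algorithm <- "random_asynchronous"
  run_swarm(features, labels, cfg, fixed_mask = fixed_mask, ...)
}
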