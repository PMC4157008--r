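test_that("the inertia schedule hits its endpoints and decreases linearly", {
  cfg <- swarm_config(k_max = 1000)
  expect_equal(inertia(0, cfg), 0.9)
  expect_equal(inertia(1000, cfg), 0.4)
  expect_equal(inertia(500, cfg), 0.65)
  w <- vapply(0:1000, inertia, numeric(1), cfg = cfg)
  expect_true(all(diff(w) < 0))
})

test_that("the v-shaped transfer is even, zero at zero, and below one", {
  expect_identical(vshape_transfer(0), 0)
  expect_equal(vshape_transfer(1), tanh(1))
  expect_equal(vshape_transfer(1), 0.76159, tolerance = 1e-5)
  v <- seq(-10, 10, by = 0.25)
  expect_equal(vshape_transfer(v), vshape_transfer(-v))
  expect_true(all(vshape_transfer(v) >= 0 & vshape_transfer(v) < 1))
})

test_that("velocity and position updates follow the update equations", {
  expect_equal(velocity_update(2, 0, 1, 3, w = 0.5, r1 = 0.5, r2 = 0.5), 5)
  expect_equal(velocity_update(7, 0, 0, 0, w = 1, r1 = 1, r2 = 1,
                               c1 = 0, c2 = 0), 7)       # null attraction
  expect_equal(velocity_update(1, 2, 2, 2, w = 0, r1 = 1, r2 = 1), 0)
  expect_equal(velocity_update(2, 0, 1, 3, w = 0.5, r1 = 0.5, r2 = 0.5,
                               v_max = 4), 4)            # clamped
  expect_equal(position_update_continuous(1, 0, 0, 30), 1)
  expect_equal(position_update_continuous(29, 5, 0, 30), 30)
  expect_equal(position_update_continuous(0, -1, 0, 30), 0)
})

test_that("binary updates never flip at zero velocity and flip when told", {
  u <- seq(0, 0.999, by = 0.01)
  expect_true(all(position_update_binary(rep(1, length(u)), 0, u) == 1))
  expect_true(all(position_update_binary(rep(0, length(u)), 0, u) == 0))
  expect_identical(position_update_binary(1, 50, 0.1), 0)   # transfer ~ 1
  expect_identical(position_update_binary(1, 2, 0.99), 1)   # u >= tanh(2)
  expect_identical(position_update_binary(0, -2, 0.9), 1)   # flip branch
})

test_that("threshold ranges are grouped by feature category", {
  r <- threshold_ranges()
  expect_equal(unname(r[, "lo"]), rep(0, 14))
  expect_equal(unname(r[1:5, "hi"]), rep(30, 5))
  expect_equal(unname(r[6:10, "hi"]), rep(781.25, 5))
  expect_equal(unname(r[11:14, "hi"]), rep(24.16, 4))
  lit <- threshold_ranges(literal_table = TRUE)
  expect_equal(unname(lit[6:12, "hi"]), rep(781.25, 7))
  expect_equal(unname(lit[13:14, "hi"]), rep(24.16, 2))
})

test_that("seeded runs are bit-reproducible and gbest never decreases", {
  ts <- small_training_set()
  for (alg in c("synchronous", "random_asynchronous")) {
    cfg <- swarm_config(n_particles = 10, k_max = 30, algorithm = alg,
                        seed = 7)
    a <- run_swarm(ts$features, ts$labels, cfg)
    b <- run_swarm(ts$features, ts$labels, cfg)
    expect_identical(a$gbest_history, b$gbest_history)
    expect_identical(a$model$mask, b$model$mask)
    expect_identical(a$model$thresholds, b$model$thresholds)
    expect_length(a$gbest_history, 31L)
    expect_true(all(diff(a$gbest_history) >= 0))
    expect_identical(a$evaluations, 10L * 31L)
  }
})

test_that("k_max = 0 scores the initial population only", {
  ts <- small_training_set()
  cfg <- swarm_config(n_particles = 8, k_max = 0, seed = 1)
  fit <- run_swarm(ts$features, ts$labels, cfg)
  expect_length(fit$gbest_history, 1L)
  expect_identical(fit$evaluations, 8L)
})

test_that("positions stay inside their ranges and bits stay binary", {
  ts <- small_training_set()
  ranges <- threshold_ranges()
  seen_bad <- FALSE
  spy <- local({
    inner <- peakswarm:::make_rule_fitness(ts$features, ts$labels)
    function(mask, thresholds) {
      if (!all(mask %in% c(TRUE, FALSE)) ||
          !all(thresholds >= ranges[, 1] - 1e-9) ||
          !all(thresholds <= ranges[, 2] + 1e-9)) seen_bad <<- TRUE
      inner(mask, thresholds)
    }
  })
  for (alg in c("synchronous", "random_asynchronous")) {
    cfg <- swarm_config(n_particles = 10, k_max = 40, algorithm = alg,
                        seed = 3)
    run_swarm(ts$features, ts$labels, cfg, fitness = spy)
  }
  expect_false(seen_bad)
})

test_that("an empty training set is an error", {
  expect_error(run_swarm(matrix(0, 0, 14), logical(0), swarm_config()),
               "empty")
})

test_that("a single-particle asynchronous swarm is a sequential optimizer", {
  ts <- small_training_set()
  cfg <- swarm_config(n_particles = 1, k_max = 25,
                      algorithm = "random_asynchronous", seed = 2)
  fit <- run_swarm(ts$features, ts$labels, cfg)
  expect_identical(fit$evaluations, 26L)
  expect_true(all(diff(fit$gbest_history) >= 0))
})

test_that("both variants optimize a smooth unimodal surface", {
  # sanity harness, not a claim about the EEG problem: freeze the mask and
  # maximize 1 - normalized squared distance to a target threshold vector
  ranges <- threshold_ranges()
  target <- ranges[, 1] + 0.3 * (ranges[, 2] - ranges[, 1])
  smooth_fitness <- function(mask, thresholds) {
    z <- (thresholds - target) / (ranges[, 2] - ranges[, 1])
    1 - mean(z^2)
  }
  for (alg in c("synchronous", "random_asynchronous")) {
    hits <- 0L
    for (s in 1:10) {
      cfg <- swarm_config(n_particles = 30, k_max = 500, algorithm = alg,
                          seed = 1000 + s)
      fit <- run_swarm(NULL, NULL, cfg, fixed_mask = 1:14,
                       fitness = smooth_fitness)
      if (fit$gbest_score >= 0.99) hits <- hits + 1L
    }
    expect_gte(hits, 9L)
  }
})

test_that("fixed-model runs freeze the binary half of every particle", {
  ts <- small_training_set()
  spy_masks <- list()
  spy <- local({
    inner <- peakswarm:::make_rule_fitness(ts$features, ts$labels)
    function(mask, thresholds) {
      spy_masks[[length(spy_masks) + 1L]] <<- which(mask)
      inner(mask, thresholds)
    }
  })
  cfg <- swarm_config(n_particles = 6, k_max = 15, seed = 9)
  fit <- run_swarm(ts$features, ts$labels, cfg,
                   fixed_mask = model_subset("dingle"), fitness = spy)
  expect_true(all(vapply(spy_masks, identical, logical(1),
                         c(5L, 6L, 11L, 12L))))
  expect_identical(which(fit$model$mask), c(5L, 6L, 11L, 12L))
})
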