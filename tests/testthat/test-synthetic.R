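test_that("terrain generation is deterministic and honours its knobs", {
  t1 <- generate_terrain(width = 20, depth = 20, seed = 3, n_objects = 5)
  t2 <- generate_terrain(width = 20, depth = 20, seed = 3, n_objects = 5)
  expect_identical(t1$map$elevation, t2$map$elevation)
  expect_identical(t1$objects, t2$objects)

  flat <- generate_terrain(width = 15, depth = 15, roughness = 0,
                           obstruction_frac = 0, seed = 4, n_objects = 4)
  expect_equal(length(unique(as.vector(flat$map$elevation))), 1)
  expect_false(any(flat$map$obstructed))
  expect_error(generate_terrain(obstruction_frac = 0.6), "below 0.5")
})

test_that("objects and start are mutually reachable on generated maps", {
  tr <- generate_terrain(width = 25, depth = 25, seed = 6, n_objects = 8)
  cells <- rbind(tr$start, as.matrix(tr$objects[, c("x", "y")]))
  f <- distance_field(tr$map, cells[1, ])
  for (i in seq_len(nrow(cells))) {
    expect_true(is.finite(f[cells[i, 1] + 1, cells[i, 2] + 1]))
    expect_true(is.finite(dijkstra(tr$map, cells[1, ],
                                   cells[i, ])$distance))
  }
})

test_that("simulated sessions respect the walkability predicate and the cap", {
  tr <- generate_terrain(width = 25, depth = 25, seed = 7, n_objects = 6)
  for (style in c("direct", "corrective", "prolonged_wanderer",
                  "late_adapter")) {
    sim <- simulate_training_session(tr, agent_policy(style), seed = 2,
                                     session_cap = 300)
    s <- sim$path$samples
    expect_lte(max(s$t), 300)
    expect_equal(s$t, seq_len(nrow(s)) - 1)        # 1 Hz sampling
    for (i in seq_len(nrow(s) - 1)) {
      a <- c(floor(s$x[i]), floor(s$y[i]))
      b <- c(floor(s$x[i + 1]), floor(s$y[i + 1]))
      expect_true(all(abs(b - a) <= 1))            # <= 1 cell per second
      if (any(a != b))
        expect_true(is_walkable_edge(tr$map, a, b))
    }
    # found events coincide with the agent standing on the object cell
    ev <- sim$events$events
    finds <- ev[ev$kind == "object_found", ]
    for (j in seq_len(nrow(finds))) {
      at <- s[s$t == finds$t[j], ]
      expect_equal(c(floor(at$x), floor(at$y)),
                   c(floor(finds$x[j]), floor(finds$y[j])))
    }
  }
})

test_that("identical seeds reproduce identical sessions", {
  tr <- generate_terrain(width = 20, depth = 20, seed = 8, n_objects = 5)
  a <- simulate_training_session(tr, agent_policy("corrective"), seed = 5)
  b <- simulate_training_session(tr, agent_policy("corrective"), seed = 5)
  expect_identical(a$path$samples, b$path$samples)
  expect_identical(a$events$events, b$events$events)
})

test_that("navigation styles produce their characteristic curve shapes", {
  tr <- generate_terrain(width = 30, depth = 30, seed = 9, n_objects = 6)
  shapes <- function(style, seed) {
    sim <- simulate_training_session(tr, agent_policy(style), seed = seed)
    segs <- segment_training_path(sim$path, sim$events)
    segs <- Filter(function(s) s$duration >= 2, segs)
    lapply(segs, function(s)
      normalize_curve(cost_difference_curve(tr$map, s)))
  }
  # late adapter: by mid-segment the drop is essentially complete
  la <- shapes("late_adapter", 11)
  late_vals <- vapply(la, function(cv) cv$values[51] / max(cv$values[1], 1),
                      numeric(1))
  expect_lt(stats::median(late_vals), 0.2)
  # prolonged wanderer: still high at the midpoint on typical segments
  pw <- shapes("prolonged_wanderer", 11)
  pw_vals <- vapply(pw, function(cv) cv$values[51] / max(cv$values[1], 1),
                    numeric(1))
  expect_gt(stats::median(pw_vals), stats::median(late_vals))
})

test_that("placement test logs respect the 3-minute cap and zero-error limit", {
  tr <- generate_terrain(width = 25, depth = 25, seed = 10, n_objects = 6)
  log <- simulate_test_session(tr, memory_error_scale = 0, seed = 3)
  ev <- log$events
  placed <- ev[ev$kind == "object_placed", ]
  starts <- ev[ev$kind == "trial_start", ]
  expect_equal(nrow(placed), 6)
  dt <- placed$t - starts$t[match(placed$object_id, starts$object_id)]
  expect_true(all(dt <= 180))
  out <- compute_outcomes(tr$map, log, tr$objects)
  expect_equal(out$y1, 6)
  expect_equal(out$y3, 0)

  noisy <- simulate_test_session(tr, memory_error_scale = 15, seed = 3)
  out2 <- compute_outcomes(tr$map, noisy, tr$objects)
  expect_lte(out2$y1, 6)
})

test_that("archetype curves separate into the four planted groups", {
  ac <- simulate_archetype_curves(600, seed = 12)
  expect_equal(dim(ac$values), c(600, 101))
  expect_equal(sort(unique(ac$truth)), 1:4)
  b <- bspline_basis(12)
  co <- spline_coefficients(ac$values, ac$grid, b)
  cl <- cluster_curves(co, 4, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cl$assignments, ac$truth), 0.9)
  expect_error(simulate_archetype_curves(10, weights = c(1, 1, 0, 0)),
               "sum to 1")
})

test_that("sofr generator: sigma = 0 and beta = 0 gives exact linear outcomes", {
  d <- simulate_sofr_data(n = 40, sigma = 0,
                          beta_fun = function(t) rep(0, length(t)),
                          seed = 13)
  Z <- model.matrix(~ age + skill, d$data)
  expect_equal(d$data$y, as.numeric(Z %*% d$gamma), tolerance = 1e-10)
})

test_that("cohort generation is reproducible and internally consistent", {
  cfg <- cohort_config(n_participants = 6, n_environments = 2,
                       map_width = 20, map_depth = 20, seed = 14)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$outcomes, co2$outcomes)
  expect_identical(co1$curve_matrix$values, co2$curve_matrix$values)
  expect_equal(nrow(co1$participants), 6)
  expect_true(all(co1$curve_matrix$meta$participant_id %in%
                    co1$participants$participant_id))
  expect_true(all(co1$outcomes$y1 >= 0 & co1$outcomes$y1 <= 12))
  # single-style cohort collapses onto one dominant flat-zero cluster
  cfg1 <- cohort_config(n_participants = 4, n_environments = 1,
                        map_width = 20, map_depth = 20,
                        policy_weights = c(direct = 1, corrective = 0,
                                           prolonged_wanderer = 0,
                                           late_adapter = 0), seed = 15)
  co3 <- generate_cohort(cfg1)
  expect_lt(max(abs(co3$curve_matrix$values)), 1e-9)
})
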