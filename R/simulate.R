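#' Agent navigation policies
#'
#' Defines the behavioural style of a simulated agent during training. The
#' four styles mirror the qualitative strategy clusters observed in curve
#' space:
#' * `direct` — walks the Dijkstra-optimal path to each object
#'   (identically-zero cost-difference curves);
#' * `corrective` — mostly optimal, but starts short random detours with
#'   probability `detour_prob` per step (shallow, gradually decreasing
#'   curves);
#' * `prolonged_wanderer` — goal-biased random walk for most of the segment
#'   before committing to the optimal path (curves that stay high past the
#'   midpoint);
#' * `late_adapter` — unbiased random walk for an early fraction
#'   `adapt_frac` of the segment, then switches to the optimal path (curves
#'   whose drop completes early).
#'
#' @param style One of `"direct"`, `"corrective"`, `"prolonged_wanderer"`,
#'   `"late_adapter"`.
#' @param detour_prob Per-step probability that `corrective` starts a detour.
#' @param wander_len Length (steps) of a corrective detour.
#' @param adapt_frac Fraction of a segment spent wandering by `late_adapter`.
#' @param wander_frac Fraction of a segment spent wandering by
#'   `prolonged_wanderer`.
#' @param goal_bias Probability that a wandering step of
#'   `prolonged_wanderer` moves optimally anyway.
#' @param order_noise Probability of picking the second-nearest (rather than
#'   nearest) remaining object as the next target.
#' @return An object of class `"agent_policy"`.
#' @export
agent_policy <- function(style = c("direct", "corrective",
                                   "prolonged_wanderer", "late_adapter"),
                         detour_prob = 0.25, wander_len = 3L,
                         adapt_frac = 0.3, wander_frac = 0.8,
                         goal_bias = 0.25, order_noise = 0.2) {
  style <- match.arg(style)
  structure(list(style = style, detour_prob = detour_prob,
                 wander_len = as.integer(wander_len),
                 adapt_frac = adapt_frac, wander_frac = wander_frac,
                 goal_bias = goal_bias, order_noise = order_noise),
            class = "agent_policy")
}

# Clamped box blur used to turn white noise into a smooth height field.
box_blur <- function(m, r = 2L) {
  w <- nrow(m); d <- ncol(m)
  acc <- matrix(0, w, d)
  for (dx in -r:r) for (dy in -r:r)
    acc <- acc + m[pmin(pmax(seq_len(w) + dx, 1L), w),
                   pmin(pmax(seq_len(d) + dy, 1L), d)]
  acc / (2 * r + 1)^2
}

#' Generate a random voxel terrain with reachable objects
#'
#' Builds a smoothed integer elevation field (white noise passed through a
#' box blur, scaled to amplitude `roughness` and shifted positive), sprinkles
#' an obstruction mask, and places `n_objects` objects plus a start cell on
#' unobstructed ground. Terrains are regenerated under fresh sub-seeds until
#' start and objects are all mutually reachable in both directions (the graph
#' is directed).
#'
#' @param width,depth Map size in cells.
#' @param roughness Elevation amplitude in blocks (0 = flat).
#' @param obstruction_frac Fraction of obstructed cells (must be < 0.5).
#' @param n_objects Number of hidden objects (default 12).
#' @param seed RNG seed; identical seeds give identical terrains.
#' @param rules A [movement_rules()] used for the reachability check.
#' @param min_separation Minimum pairwise octile separation between objects.
#' @param max_retries Regeneration attempts before giving up.
#' @return List with `map` (a [terrain_map()]), `objects` (data frame
#'   `object_id, x, y, z`), and `start` (`c(x, y)`).
#' @export
generate_terrain <- function(width = 40L, depth = 40L, roughness = 2,
                             obstruction_frac = 0.10, n_objects = 12L,
                             seed = 1L, rules = movement_rules(),
                             min_separation = 6, max_retries = 50L) {
  if (obstruction_frac >= 0.5)
    stop("obstruction_frac must be below 0.5 to keep maps connected",
         call. = FALSE)
  attempt <- function() {
      noise <- matrix(stats::rnorm(width * depth), width, depth)
      sm <- box_blur(box_blur(noise, 2L), 2L)
      if (roughness > 0 && stats::sd(sm) > 0)
        sm <- sm / stats::sd(sm) * roughness
      else sm <- sm * 0
      elev <- round(sm)
      elev <- elev - min(elev) + 1L
      obstructed <- matrix(stats::runif(width * depth) < obstruction_frac,
                           width, depth)
      open <- which(!obstructed)
      if (length(open) < n_objects + 1L) return(NULL)
      # greedy object placement with a minimum separation
      cand <- sample(open)
      chosen <- integer(0)
      for (id in cand) {
        x <- (id - 1L) %% width; y <- (id - 1L) %/% width
        far <- all(vapply(chosen, function(c0) {
          octile_distance(c((c0 - 1L) %% width, (c0 - 1L) %/% width),
                          c(x, y)) >= min_separation
        }, logical(1)))
        if (far) chosen <- c(chosen, id)
        if (length(chosen) == n_objects + 1L) break
      }
      if (length(chosen) < n_objects + 1L) return(NULL)
      map <- terrain_map(elev, obstructed)
      start_id <- chosen[n_objects + 1L]
      obj_ids <- chosen[seq_len(n_objects)]
      all_ids <- c(start_id, obj_ids)
      tg <- terrain_graph(map, rules)
      d_out <- igraph::distances(tg$graph, v = all_ids[1], to = all_ids,
                                 mode = "out")
      d_in <- igraph::distances(tg$graph, v = all_ids[1], to = all_ids,
                                mode = "in")
      if (any(!is.finite(d_out)) || any(!is.finite(d_in))) return(NULL)
      xy <- id_to_xy(map, obj_ids)
      list(map = map,
           objects = data.frame(
             object_id = paste0("obj", seq_len(n_objects)),
             x = xy[, "x"], y = xy[, "y"],
             z = elev[cbind(xy[, "x"] + 1L, xy[, "y"] + 1L)]),
           start = c((start_id - 1L) %% width, (start_id - 1L) %/% width))
  }
  for (try in seq_len(max_retries)) {
    sub <- (seed + 7919L * (try - 1L)) %% .Machine$integer.max
    res <- with_seed(sub, attempt())
    if (!is.null(res)) return(res)
  }
  stop("could not generate a connected terrain in ", max_retries,
       " attempts", call. = FALSE)
}

# Walkable out-neighbour list for fast stepping.
neighbour_list <- function(map, rules) {
  tg <- terrain_graph(map, rules)
  adj <- igraph::as_adj_list(tg$graph, mode = "out")
  lapply(adj, as.integer)
}

#' Simulate one training session of an agent
#'
#' The agent starts at `start`, repeatedly picks the nearest unfound object
#' (with probability `order_noise`, the second nearest) and moves toward it
#' one cell per second according to its [agent_policy()]. Position samples
#' are emitted at 1 Hz (cell centres, i.e. block + 0.5) together with
#' `session_start` / `object_found` / `session_end` events; the session is
#' truncated at `session_cap` seconds. Every generated step satisfies the
#' walkability predicate by construction.
#'
#' @param terrain A list as returned by [generate_terrain()] (`map`,
#'   `objects`, `start`).
#' @param policy An [agent_policy()].
#' @param seed RNG seed.
#' @param rules A [movement_rules()].
#' @param session_cap Session length cap in seconds (default 600 = 10 min).
#' @param participant_id,session_id Identifiers stamped on the outputs.
#' @return List with `path` (a `"tracked_path"`) and `events`
#'   (an `"event_log"`).
#' @export
simulate_training_session <- function(terrain, policy, seed = 1L,
                                      rules = movement_rules(),
                                      session_cap = 600L,
                                      participant_id = "p1",
                                      session_id = "training1") {
  map <- terrain$map
  adj <- neighbour_list(map, rules)
  elev <- as.vector(map$elevation)
  w <- map$width
  tg <- terrain_graph(map, rules)
  obj_ids <- cell_id(map, terrain$objects$x, terrain$objects$y)

  step_w <- function(a, b) {
    dx <- (b - 1L) %% w - (a - 1L) %% w
    dy <- (b - 1L) %/% w - (a - 1L) %/% w
    dz <- elev[b] - elev[a]
    sqrt(dx^2 + dy^2) + rules$alpha_up * max(dz, 0) +
      rules$alpha_down * max(-dz, 0)
  }
  direct_step <- function(pos, field) {
    nb <- adj[[pos]]
    costs <- vapply(nb, function(n) step_w(pos, n) + field[n], numeric(1))
    nb[which.min(costs)]
  }
  random_step <- function(pos) {
    nb <- adj[[pos]]
    if (!length(nb)) return(pos)
    nb[sample.int(length(nb), 1L)]
  }

  with_seed(seed, {
    pos <- cell_id(map, terrain$start[1], terrain$start[2])
    unfound <- seq_len(nrow(terrain$objects))
    t <- 0L
    pos_trace <- integer(session_cap + 1L)
    pos_trace[1L] <- pos
    ev <- list(data.frame(t = 0, kind = "session_start", object_id = NA,
                          x = terrain$start[1] + 0.5,
                          y = terrain$start[2] + 0.5,
                          z = elev[pos]))
    while (length(unfound) && t < session_cap) {
      dists <- igraph::distances(tg$graph, v = pos, to = obj_ids[unfound],
                                 mode = "out")[1, ]
      ord <- order(dists)
      pick <- if (length(ord) > 1 && stats::runif(1) < policy$order_noise)
        ord[2] else ord[1]
      target_i <- unfound[pick]
      target <- obj_ids[target_i]
      field <- as.vector(distance_field(
        map, c(terrain$objects$x[target_i], terrain$objects$y[target_i]),
        rules))
      wander_left <- switch(policy$style,
        direct = 0L,
        corrective = 0L,
        late_adapter = max(0L, round(policy$adapt_frac /
                                       (1 - policy$adapt_frac) *
                                       field[pos] / 1.2)),
        prolonged_wanderer = max(0L, round(policy$wander_frac /
                                             (1 - policy$wander_frac) *
                                             field[pos] / 1.2)))
      detour_left <- 0L
      while (pos != target && t < session_cap) {
        if (wander_left > 0L) {
          pos <- if (policy$style == "prolonged_wanderer" &&
                     stats::runif(1) < policy$goal_bias)
            direct_step(pos, field) else random_step(pos)
          wander_left <- wander_left - 1L
        } else if (policy$style == "corrective") {
          if (detour_left == 0L && stats::runif(1) < policy$detour_prob)
            detour_left <- policy$wander_len
          if (detour_left > 0L) {
            pos <- random_step(pos)
            detour_left <- detour_left - 1L
          } else pos <- direct_step(pos, field)
        } else {
          pos <- direct_step(pos, field)
        }
        t <- t + 1L
        pos_trace[t + 1L] <- pos
      }
      if (pos == target) {
        ev[[length(ev) + 1L]] <- data.frame(
          t = t, kind = "object_found",
          object_id = terrain$objects$object_id[target_i],
          x = terrain$objects$x[target_i] + 0.5,
          y = terrain$objects$y[target_i] + 0.5,
          z = terrain$objects$z[target_i])
        unfound <- unfound[unfound != target_i]
      }
    }
    ev[[length(ev) + 1L]] <- data.frame(
      t = t, kind = "session_end", object_id = NA,
      x = (pos_trace[t + 1L] - 1L) %% w + 0.5,
      y = (pos_trace[t + 1L] - 1L) %/% w + 0.5,
      z = elev[pos_trace[t + 1L]])
    ids <- pos_trace[seq_len(t + 1L)]
    samples <- data.frame(t = 0:t,
                          x = (ids - 1L) %% w + 0.5,
                          y = (ids - 1L) %/% w + 0.5,
                          z = elev[ids])
    events <- do.call(rbind, ev)
    list(
      path = structure(list(participant_id = participant_id,
                            session_id = session_id, samples = samples),
                       class = "tracked_path"),
      events = structure(list(participant_id = participant_id,
                              session_id = session_id, events = events),
                         class = "event_log"))
  })
}

#' Simulate a placement-test session
#'
#' For each object (in random order) the agent is teleported to one of four
#' start cells on the map edge (`trial_start`), then places the object at the
#' true location displaced by rounded Gaussian noise of scale
#' `memory_error_scale` (clamped to the map and moved to the nearest
#' unobstructed cell); the placement time is gamma-distributed and capped at
#' 180 s. `memory_error_scale = 0` reproduces every true location exactly.
#'
#' @inheritParams simulate_training_session
#' @param memory_error_scale Standard deviation (cells) of the placement
#'   error.
#' @return An `"event_log"` with `trial_start` / `object_placed` pairs.
#' @export
simulate_test_session <- function(terrain, memory_error_scale = 3,
                                  seed = 1L, rules = movement_rules(),
                                  participant_id = "p1",
                                  session_id = "test") {
  map <- terrain$map
  w <- map$width; d <- map$depth
  open <- which(!as.vector(map$obstructed))
  nearest_open <- function(x, y) {
    xy <- id_to_xy(map, open)
    i <- which.min(pmax(abs(xy[, "x"] - x), abs(xy[, "y"] - y)))
    c(xy[i, "x"], xy[i, "y"])
  }
  starts <- rbind(nearest_open(0, d %/% 2), nearest_open(w - 1, d %/% 2),
                  nearest_open(w %/% 2, 0), nearest_open(w %/% 2, d - 1))
  with_seed(seed, {
    ord <- sample.int(nrow(terrain$objects))
    t <- 0
    rows <- list()
    for (i in ord) {
      st <- starts[sample.int(4, 1), ]
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, kind = "trial_start",
        object_id = terrain$objects$object_id[i],
        x = st[1] + 0.5, y = st[2] + 0.5,
        z = map$elevation[st[1] + 1L, st[2] + 1L])
      dt <- min(180, round(5 + stats::rgamma(1, shape = 2, scale = 25)))
      px <- terrain$objects$x[i] + round(stats::rnorm(1, sd = memory_error_scale))
      py <- terrain$objects$y[i] + round(stats::rnorm(1, sd = memory_error_scale))
      px <- min(max(px, 0L), w - 1L); py <- min(max(py, 0L), d - 1L)
      if (map$obstructed[px + 1L, py + 1L]) {
        p <- nearest_open(px, py); px <- p[1]; py <- p[2]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        t = t + dt, kind = "object_placed",
        object_id = terrain$objects$object_id[i],
        x = px + 0.5, y = py + 0.5,
        z = map$elevation[px + 1L, py + 1L])
      t <- t + dt
    }
    structure(list(participant_id = participant_id, session_id = session_id,
                   events = do.call(rbind, rows)),
              class = "event_log")
  })
}

#' Synthetic normalised curves from the four strategy archetypes
#'
#' Draws curves directly in curve space (no agent simulation): each curve is
#' one of four mean shapes — flat-zero, shallow-decreasing, high-until-late,
#' early-sharp-drop — with a per-curve amplitude jitter and additive
#' Gaussian noise. Used to validate the functional clustering stage against
#' a known partition.
#'
#' @param n Number of curves.
#' @param weights Mixture weights over the four archetypes (direct,
#'   corrective, prolonged_wanderer, late_adapter); must sum to 1.
#' @param amplitude Typical curve starting height (path-cost units).
#' @param noise_sd Additive noise standard deviation per grid point.
#' @param grid Evaluation grid.
#' @param seed RNG seed.
#' @return List with `values` (n x grid matrix), `truth` (archetype index
#'   1..4 per curve), `labels` (style names), `grid`.
#' @export
simulate_archetype_curves <- function(n = 2000L,
                                      weights = c(0.45, 0.30, 0.15, 0.10),
                                      amplitude = 50, noise_sd = 3,
                                      grid = seq(0, 100, length.out = 101),
                                      seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  s <- grid / max(grid)
  shapes <- rbind(
    direct = rep(0, length(s)),
    corrective = 0.5 * (1 - s),
    prolonged_wanderer = pmin(1, (1 - s) / 0.2),
    late_adapter = pmax(0, 1 - s / 0.3))
  with_seed(seed, {
    truth <- sample.int(4, n, replace = TRUE, prob = weights)
    amp <- amplitude * stats::runif(n, 0.8, 1.2)
    vals <- shapes[truth, , drop = FALSE] * amp +
      matrix(stats::rnorm(n * length(s), sd = noise_sd), n)
    list(values = vals, truth = truth,
         labels = rownames(shapes)[truth], grid = grid)
  })
}

#' Simulate data from the scalar-on-functional generative model
#'
#' Draws scalar covariates (age, Minecraft skill), a functional covariate
#' per participant, and generates the outcome as
#' `y = z' gamma + integral X(t) beta(t) dt + N(0, sigma^2)` with trapezoid
#' quadrature on the grid — the same quadrature [sofr()] uses, so the fitted
#' model is correctly specified and parameter recovery can be tested.
#'
#' With `curve_type = "smooth"` (default) the curves are random smooth
#' functions with full-rank variation in basis space (iid coefficients on a
#' 12-function cubic B-spline), which makes `beta(t)` identifiable — the
#' right design for recovery and coverage experiments. `"archetype"` draws
#' the four navigation-strategy shapes instead: more realistic, but the
#' curves then span a low-dimensional space and `beta(t)` is only
#' identified up to that span.
#'
#' @param n Number of participants.
#' @param gamma Named true scalar coefficients on the columns of
#'   `model.matrix(~ age + skill)`.
#' @param beta_fun True functional coefficient as a function of grid time.
#' @param sigma Residual standard deviation.
#' @param grid Curve grid.
#' @param curve_type `"smooth"` (identifiable design) or `"archetype"`.
#' @param curve_scale Coefficient standard deviation of the smooth curves.
#' @param seed RNG seed.
#' @return List with `data` (age, skill, y), `curves`, `grid`, `gamma`,
#'   `beta` (true beta on the grid), `beta_fun`.
#' @export
simulate_sofr_data <- function(n = 200L,
                               gamma = c("(Intercept)" = 2, age = 0.05,
                                         skillIntermediate = -1,
                                         skillNovice = -1.5),
                               beta_fun = function(t) 0.01 * sin(pi * t / 100),
                               sigma = 1,
                               grid = seq(0, 100, length.out = 101),
                               curve_type = c("smooth", "archetype"),
                               curve_scale = 20,
                               seed = 1L) {
  curve_type <- match.arg(curve_type)
  with_seed(seed, {
    age <- round(stats::runif(n, 18, 40))
    skill <- factor(sample(c("Expert", "Intermediate", "Novice"), n,
                           replace = TRUE),
                    levels = c("Expert", "Intermediate", "Novice"))
    curves <- if (curve_type == "smooth") {
      cb <- bspline_basis(12L, range = range(grid))
      matrix(stats::rnorm(n * cb$n_basis, sd = curve_scale), n) %*%
        t(eval_basis(cb, grid))
    } else simulate_archetype_curves(
      n, grid = grid, seed = sample.int(.Machine$integer.max, 1))$values
    Z <- stats::model.matrix(~ age + skill,
                             data.frame(age = age, skill = skill))
    stopifnot(identical(colnames(Z), names(gamma)))
    qw <- trapezoid_weights(grid)
    integral <- drop(curves %*% (beta_fun(grid) * qw))
    y <- drop(Z %*% gamma) + integral + stats::rnorm(n, sd = sigma)
    list(data = data.frame(age = age, skill = skill, y = y),
         curves = curves, grid = grid, gamma = gamma,
         beta = beta_fun(grid), beta_fun = beta_fun)
  })
}

#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic cohort: terrain geometry, session
#' structure, the policy mixture over the four navigation styles, and the
#' generative scalar-on-functional outcome models. All randomness descends
#' from `seed` through fixed sub-streams, so identical configurations give
#' identical cohorts.
#'
#' @param n_participants Cohort size.
#' @param n_environments Number of distinct terrains (participants are
#'   assigned round-robin).
#' @param map_width,map_depth Terrain size in cells.
#' @param roughness Elevation amplitude in blocks.
#' @param obstruction_frac Obstructed-cell fraction.
#' @param n_objects Hidden objects per environment (default 12).
#' @param session_cap Training session cap in seconds (default 600).
#' @param policy_weights Mixture weights assigning participants to the four
#'   navigation styles.
#' @param memory_error_scale Placement-error scale of the test simulator.
#' @param t_unified,grid_size Unified curve time scale and grid resolution.
#' @param cutoff Low/high-cost segment cutoff (default 70).
#' @param outcome_models Per-outcome generative coefficients: a named list
#'   (`y1`, `y2`, `y3`) of lists with `gamma` (named vector on the columns of
#'   `model.matrix(~ age + skill)`), `beta_fun`, `sigma`. Outcomes use
#'   disjoint covariate effects so their correlations stay near zero.
#' @param seed Master seed.
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_participants = 50L, n_environments = 4L,
                          map_width = 40L, map_depth = 40L, roughness = 2,
                          obstruction_frac = 0.10, n_objects = 12L,
                          session_cap = 600L,
                          policy_weights = c(direct = 0.45,
                                             corrective = 0.30,
                                             prolonged_wanderer = 0.15,
                                             late_adapter = 0.10),
                          memory_error_scale = 3,
                          t_unified = 100, grid_size = 101L,
                          cutoff = 70,
                          outcome_models = NULL,
                          seed = 1L) {
  if (abs(sum(policy_weights) - 1) > 1e-8)
    stop("policy_weights must sum to 1", call. = FALSE)
  if (is.null(outcome_models)) outcome_models <- list(
    y1 = list(gamma = c("(Intercept)" = 9, age = 0,
                        skillIntermediate = -1.2, skillNovice = -1.8),
              beta_fun = function(t) -0.004 * sin(pi * t / 100), sigma = 1.2),
    y2 = list(gamma = c("(Intercept)" = 55, age = 0.5,
                        skillIntermediate = 0, skillNovice = 0),
              beta_fun = function(t) rep(0, length(t)), sigma = 8),
    y3 = list(gamma = c("(Intercept)" = 4, age = 0,
                        skillIntermediate = 0.9, skillNovice = 1.25),
              beta_fun = function(t) 0.004 * t / 100, sigma = 1.3))
  structure(list(n_participants = as.integer(n_participants),
                 n_environments = as.integer(n_environments),
                 map_width = as.integer(map_width),
                 map_depth = as.integer(map_depth),
                 roughness = roughness,
                 obstruction_frac = obstruction_frac,
                 n_objects = as.integer(n_objects),
                 session_cap = as.integer(session_cap),
                 policy_weights = policy_weights,
                 memory_error_scale = memory_error_scale,
                 t_unified = t_unified, grid_size = as.integer(grid_size),
                 cutoff = cutoff, outcome_models = outcome_models,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative process: terrains per environment, participant
#' covariates and navigation styles, two training sessions per participant
#' (trajectories + event logs), a placement-test log, per-segment normalised
#' cost-difference curves, and outcomes `y1, y2, y3` drawn from the
#' scalar-on-functional generative model using each participant's own mean
#' low-cost curve as the functional covariate.
#'
#' @param config A [cohort_config()].
#' @param rules A [movement_rules()].
#' @return List with `config`, `terrains`, `participants` (covariates,
#'   style, environment), `sessions` (per participant/session paths and
#'   event logs), `test_logs`, `curves` (list of `"normalized_curve"`),
#'   `curve_matrix`, `outcomes` (data frame `participant_id, y1, y2, y3`),
#'   `mean_curves`, `excluded_segments` (diagnostics).
#' @export
generate_cohort <- function(config = cohort_config(),
                            rules = movement_rules()) {
  cfg <- config
  terrains <- lapply(seq_len(cfg$n_environments), function(e)
    generate_terrain(cfg$map_width, cfg$map_depth, cfg$roughness,
                     cfg$obstruction_frac, cfg$n_objects,
                     seed = (cfg$seed + 1000L + e) %% .Machine$integer.max,
                     rules = rules))

  styles <- names(cfg$policy_weights)
  participants <- with_seed(cfg$seed + 500L, data.frame(
    participant_id = sprintf("p%03d", seq_len(cfg$n_participants)),
    environment = rep(seq_len(cfg$n_environments),
                      length.out = cfg$n_participants),
    style = sample(styles, cfg$n_participants, replace = TRUE,
                   prob = cfg$policy_weights),
    age = round(stats::runif(cfg$n_participants, 18, 40)),
    sex = factor(sample(c("Male", "Female", "Other"), cfg$n_participants,
                        replace = TRUE, prob = c(0.48, 0.48, 0.04)),
                 levels = c("Male", "Female", "Other")),
    game_experience = factor(
      sample(c("Both", "FirstPerson", "ThirdPerson", "Neither"),
             cfg$n_participants, replace = TRUE,
             prob = c(0.4, 0.25, 0.15, 0.2)),
      levels = c("Both", "FirstPerson", "ThirdPerson", "Neither")),
    skill = factor(sample(c("Expert", "Intermediate", "Novice"),
                          cfg$n_participants, replace = TRUE,
                          prob = c(0.3, 0.4, 0.3)),
                   levels = c("Expert", "Intermediate", "Novice")),
    weekly_hours = round(stats::rgamma(cfg$n_participants, shape = 2,
                                       scale = 4), 1)))

  sessions <- list()
  test_logs <- list()
  curves <- list()
  excluded <- list()
  for (i in seq_len(cfg$n_participants)) {
    pid <- participants$participant_id[i]
    env <- participants$environment[i]
    terr <- terrains[[env]]
    policy <- agent_policy(participants$style[i])
    for (s in 1:2) {
      sid <- paste0("training", s)
      sim <- simulate_training_session(
        terr, policy,
        seed = (cfg$seed + 10000L + i * 10L + s) %% .Machine$integer.max,
        rules = rules, session_cap = cfg$session_cap,
        participant_id = pid, session_id = sid)
      sessions[[paste(pid, sid, sep = ".")]] <- sim
      segs <- segment_training_path(sim$path, sim$events)
      for (seg in segs) {
        cv <- tryCatch(cost_difference_curve(terr$map, seg, rules),
                       voxelnav_unreachable_segment = function(e) e)
        if (inherits(cv, "condition")) {
          excluded[[length(excluded) + 1L]] <-
            data.frame(participant_id = pid, session_id = sid,
                       reason = conditionMessage(cv))
          next
        }
        if (cv$duration <= 0) next
        nc <- normalize_curve(cv, cfg$t_unified, cfg$grid_size)
        nc$environment <- env
        curves[[length(curves) + 1L]] <- nc
      }
    }
    test_logs[[pid]] <- simulate_test_session(
      terr, cfg$memory_error_scale,
      seed = (cfg$seed + 20000L + i) %% .Machine$integer.max,
      rules = rules, participant_id = pid)
  }

  cm <- curve_matrix(curves)
  cls <- classify_segment(cm$meta$optimal_start_cost, cfg$cutoff)
  ids <- participants$participant_id
  G <- cfg$grid_size
  mean_curves <- matrix(NA_real_, length(ids), G,
                        dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    low <- cm$meta$participant_id == ids[i] & cls == "low"
    if (any(low)) mean_curves[i, ] <- colMeans(cm$values[low, , drop = FALSE])
  }

  Z <- stats::model.matrix(~ age + skill, participants)
  qw <- trapezoid_weights(cm$grid)
  X0 <- mean_curves
  X0[is.na(X0)] <- 0        # excluded participants get no functional signal
  outcomes <- with_seed(cfg$seed + 900L, {
    out <- data.frame(participant_id = ids)
    for (k in names(cfg$outcome_models)) {
      m <- cfg$outcome_models[[k]]
      out[[k]] <- drop(Z %*% m$gamma) +
        drop(X0 %*% (m$beta_fun(cm$grid) * qw)) +
        stats::rnorm(length(ids), sd = m$sigma)
    }
    out
  })
  outcomes$y1 <- pmin(pmax(round(outcomes$y1), 0L), cfg$n_objects)

  list(config = cfg, terrains = terrains, participants = participants,
       sessions = sessions, test_logs = test_logs, curves = curves,
       curve_matrix = cm, outcomes = outcomes, mean_curves = mean_curves,
       excluded_segments = if (length(excluded)) do.call(rbind, excluded)
       else data.frame(participant_id = character(),
                       session_id = character(), reason = character()))
}
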