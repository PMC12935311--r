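# Independent shortest-path oracle: exhaustive depth-first enumeration of
# simple paths with cost-bound pruning. Walkability and weights are coded
# directly from the movement model (no package internals), so agreement with
# dijkstra() is a genuine cross-check.
oracle_shortest <- function(elev, obs, from, to,
                            alpha_up = 2, alpha_down = 1,
                            max_climb = 2, max_fall = 3) {
  w <- nrow(elev); d <- ncol(elev)
  if (obs[from[1] + 1, from[2] + 1] || obs[to[1] + 1, to[2] + 1]) return(Inf)
  best <- Inf
  offsets <- cbind(dx = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dy = c(-1, 0, 1, -1, 1, -1, 0, 1))
  rec <- function(x, y, cost, visited) {
    if (cost >= best) return(invisible(NULL))
    if (x == to[1] && y == to[2]) {
      best <<- cost
      return(invisible(NULL))
    }
    nx <- x + offsets[, "dx"]; ny <- y + offsets[, "dy"]
    ok <- nx >= 0 & nx < w & ny >= 0 & ny < d
    # explore promising directions first so pruning bites early
    ord <- order(pmax(abs(to[1] - nx), abs(to[2] - ny)) +
                   (sqrt(2) - 1) * pmin(abs(to[1] - nx), abs(to[2] - ny)))
    for (k in ord) {
      if (!ok[k]) next
      i <- nx[k] + 1; j <- ny[k] + 1
      if (visited[i, j] || obs[i, j]) next
      dz <- elev[i, j] - elev[x + 1, y + 1]
      if (dz > max_climb || dz < -max_fall) next
      wgt <- sqrt(offsets[k, "dx"]^2 + offsets[k, "dy"]^2) +
        alpha_up * max(dz, 0) + alpha_down * max(-dz, 0)
      visited[i, j] <- TRUE
      rec(nx[k], ny[k], cost + wgt, visited)
      visited[i, j] <- FALSE
    }
    invisible(NULL)
  }
  visited <- matrix(FALSE, w, d)
  visited[from[1] + 1, from[2] + 1] <- TRUE
  rec(from[1], from[2], 0, visited)
  unname(best)
}

random_small_terrain <- function(seed, size_range = 3:5, obs_prob = 0.15,
                                 zmax = 4) {
  set.seed(seed)
  pick <- function(r) if (length(r) == 1) r else sample(r, 1)
  w <- pick(size_range); d <- pick(size_range)
  elev <- matrix(sample.int(zmax, w * d, replace = TRUE), w, d)
  obs <- matrix(runif(w * d) < obs_prob, w, d)
  terrain_map(elev, obs)
}

# A 5x5 flat map with a wall through the middle forcing a detour.
walled_map <- function() {
  obs <- matrix(FALSE, 5, 5)
  obs[3, 1:4] <- TRUE
  terrain_map(matrix(1L, 5, 5), obs)
}

# Memoised medium synthetic cohort shared by the heavier tests.
.cohort_cache <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.cohort_cache$co))
    .cohort_cache$co <- generate_cohort(
      cohort_config(n_participants = 50L, seed = 20260925L))
  .cohort_cache$co
}

# Tiny hand-built path/event logs used by the IO and outcome tests.
toy_path_df <- function() {
  data.frame(participant_id = "p1", session_id = "training1",
             t = 0:6,
             x = c(0.5, 1.5, 2.5, 3.5, 3.5, 4.5, 5.5),
             y = c(0.5, 0.5, 0.5, 0.5, 1.5, 1.5, 1.5),
             z = 1)
}

toy_event_df <- function() {
  data.frame(participant_id = "p1", session_id = "training1",
             t = c(0, 3, 6),
             kind = c("session_start", "object_found", "object_found"),
             object_id = c(NA, "objA", "objB"),
             x = c(0.5, 3.5, 5.5), y = c(0.5, 0.5, 1.5), z = 1)
}
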