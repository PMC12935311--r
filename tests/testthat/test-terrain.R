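test_that("walkability enforces obstruction, adjacency and height limits", {
  elev <- matrix(1L, 4, 4)
  elev[2, 1] <- 4L   # +3 cliff at (1, 0)
  elev[3, 1] <- 1L
  obs <- matrix(FALSE, 4, 4)
  obs[2, 2] <- TRUE  # water at (1, 1)
  m <- terrain_map(elev, obs)

  expect_false(is_walkable_edge(m, c(0, 0), c(1, 0)))  # +3 > max_climb 2
  expect_true(is_walkable_edge(m, c(1, 0), c(2, 0)))   # -3 fall allowed
  elev2 <- matrix(1L, 4, 4); elev2[1, 1] <- 5L
  m2 <- terrain_map(elev2)
  expect_false(is_walkable_edge(m2, c(0, 0), c(1, 0))) # -4 beyond max_fall
  expect_false(is_walkable_edge(m, c(0, 0), c(2, 0)))  # two cells apart
  expect_false(is_walkable_edge(m, c(0, 1), c(1, 1)))  # target obstructed
  expect_false(is_walkable_edge(m, c(0, 0), c(0, 0)))  # no self loop
  expect_error(block(m, 7, 0), "bounds")
})

test_that("walkability is directed when limits differ", {
  elev <- matrix(1L, 2, 1); elev[2, 1] <- 4L
  m <- terrain_map(elev)
  expect_false(is_walkable_edge(m, c(0, 0), c(1, 0)))  # +3 climb barred
  expect_true(is_walkable_edge(m, c(1, 0), c(0, 0)))   # -3 fall fine
})

test_that("edge weights combine 2D distance with asymmetric vertical cost", {
  flat <- terrain_map(matrix(1L, 3, 3))
  expect_equal(edge_weight(flat, c(0, 0), c(1, 0)), 1.0)
  expect_equal(edge_weight(flat, c(0, 0), c(1, 1)), sqrt(2))
  elev <- matrix(1L, 3, 3); elev[2, 1] <- 3L
  m <- terrain_map(elev)
  expect_equal(edge_weight(m, c(0, 0), c(1, 0)), 1 + 2 * 2.0)  # up: alpha_up
  expect_equal(edge_weight(m, c(1, 0), c(0, 0)), 1 + 2 * 1.0)  # down
  expect_error(edge_weight(flat, c(0, 0), c(2, 0)), "not walkable")
})

test_that("dijkstra matches the octile closed form on flat open ground", {
  m <- terrain_map(matrix(1L, 6, 6))
  expect_equal(dijkstra(m, c(0, 0), c(3, 5))$distance,
               5 + 3 * (sqrt(2) - 1), tolerance = 1e-12)
  p <- dijkstra(m, c(2, 2), c(2, 2))
  expect_equal(p$distance, 0)
  expect_equal(nrow(p$blocks), 1)
})

test_that("dijkstra routes around obstructions and matches enumeration", {
  m <- walled_map()
  got <- dijkstra(m, c(0, 2), c(4, 2))
  want <- oracle_shortest(m$elevation, m$obstructed, c(0, 2), c(4, 2))
  expect_equal(got$distance, want, tolerance = 1e-9)
  expect_gt(got$distance, octile_distance(c(0, 2), c(4, 2)))
  # path itself is consistent: edges walkable, weights sum to distance
  b <- got$blocks
  wsum <- 0
  for (i in seq_len(nrow(b) - 1)) {
    expect_true(is_walkable_edge(m, c(b$x[i], b$y[i]),
                                 c(b$x[i + 1], b$y[i + 1])))
    wsum <- wsum + edge_weight(m, c(b$x[i], b$y[i]),
                               c(b$x[i + 1], b$y[i + 1]))
  }
  expect_equal(wsum, got$distance, tolerance = 1e-9)
})

test_that("unreachable targets are flagged, not errors", {
  obs <- matrix(FALSE, 5, 5); obs[3, ] <- TRUE  # full wall
  m <- terrain_map(matrix(1L, 5, 5), obs)
  r <- dijkstra(m, c(0, 0), c(4, 0))
  expect_false(r$reachable)
  expect_identical(r$distance, Inf)
  expect_equal(nrow(r$blocks), 0)
})

test_that("ramp distances are asymmetric by the up/down cost difference", {
  rules <- movement_rules(alpha_up = 2, alpha_down = 1)
  ramp <- terrain_map(matrix(1:4, 4, 1))
  up <- dijkstra(ramp, c(0, 0), c(3, 0), rules)$distance
  dn <- dijkstra(ramp, c(3, 0), c(0, 0), rules)$distance
  expect_equal(up - dn, 3 * (2 - 1), tolerance = 1e-12)
  expect_equal(up, 3 + 3 * 2)
})

test_that("distance_field equals pairwise dijkstra on the reversed graph", {
  m <- random_small_terrain(42, size_range = 6, obs_prob = 0.1)
  f <- distance_field(m, c(3, 3))
  expect_equal(f[4, 4], 0)
  for (x in 0:5) for (y in 0:5) {
    expect_equal(f[x + 1, y + 1],
                 dijkstra(m, c(x, y), c(3, 3))$distance, tolerance = 1e-9)
  }
})

test_that("triangle inequality and alpha_up monotonicity hold", {
  m <- random_small_terrain(7, size_range = 5, obs_prob = 0.1, zmax = 3)
  set.seed(1)
  open <- which(!m$obstructed) - 1L
  pts <- cbind(open %% m$width, open %/% m$width)
  for (r in 1:20) {
    abc <- pts[sample(nrow(pts), 3), , drop = FALSE]
    dab <- dijkstra(m, abc[1, ], abc[2, ])$distance
    dbc <- dijkstra(m, abc[2, ], abc[3, ])$distance
    dac <- dijkstra(m, abc[1, ], abc[3, ])$distance
    if (is.finite(dab) && is.finite(dbc))
      expect_lte(dac, dab + dbc + 1e-9)
  }
  cheap <- movement_rules(alpha_up = 1.5, alpha_down = 1)
  dear <- movement_rules(alpha_up = 4, alpha_down = 1)
  for (r in 1:10) {
    ab <- pts[sample(nrow(pts), 2), , drop = FALSE]
    expect_lte(dijkstra(m, ab[1, ], ab[2, ], cheap)$distance,
               dijkstra(m, ab[1, ], ab[2, ], dear)$distance + 1e-9)
  }
})

test_that("reversing direction swaps the roles of up and down cost", {
  # with symmetric climb/fall limits, path reversal is a cost-preserving
  # bijection once alpha_up and alpha_down trade places
  m <- random_small_terrain(9, size_range = 5, obs_prob = 0.1, zmax = 3)
  r_fwd <- movement_rules(alpha_up = 2, alpha_down = 1,
                          max_climb = 3, max_fall = 3)
  r_swp <- movement_rules(alpha_up = 2, alpha_down = 1,
                          max_climb = 3, max_fall = 3)
  set.seed(2)
  open <- which(!m$obstructed) - 1L
  pts <- cbind(open %% m$width, open %/% m$width)
  for (r in 1:10) {
    ab <- pts[sample(nrow(pts), 2), , drop = FALSE]
    d_ab <- dijkstra(m, ab[1, ], ab[2, ], r_fwd)$distance
    # same journey backwards, scored on the mirrored terrain (-elevation)
    m_neg <- terrain_map(-m$elevation, m$obstructed)
    d_ba_mirror <- dijkstra(m_neg, ab[2, ], ab[1, ], r_swp)$distance
    expect_equal(d_ab, d_ba_mirror, tolerance = 1e-9)
  }
})

test_that("terrain maps round-trip through JSON and delimited text", {
  m <- random_small_terrain(5, size_range = 4:6, obs_prob = 0.2)
  jf <- tempfile(fileext = ".json")
  write_terrain(m, jf)
  m2 <- read_terrain(jf)
  expect_identical(m2$elevation, m$elevation)
  expect_identical(m2$obstructed, m$obstructed)

  ef <- tempfile(); of <- tempfile()
  write.table(t(m$elevation), ef, row.names = FALSE, col.names = FALSE)
  write.table(t(m$obstructed * 1L), of, row.names = FALSE, col.names = FALSE)
  m3 <- read_terrain_matrices(ef, of)
  expect_identical(m3$elevation, m$elevation)
  expect_identical(m3$obstructed, m$obstructed)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(width = 2, depth = 2, elevation = c(1, 2, 3)),
                       bad, auto_unbox = TRUE)
  expect_error(read_terrain(bad), "length")
})
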