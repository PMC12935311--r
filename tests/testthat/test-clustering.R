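test_that("B-spline basis is a partition of unity with correct dimensions", {
  b <- bspline_basis(12)
  x <- seq(0, 100, length.out = 57)
  B <- eval_basis(b, x)
  expect_equal(dim(B), c(57, 12))
  expect_equal(rowSums(B), rep(1, 57), tolerance = 1e-12)
  expect_error(bspline_basis(3), "at least the spline order")
})

test_that("the curvature penalty annihilates linear functions only", {
  b <- bspline_basis(10)
  P <- basis_penalty(b)
  expect_equal(P, t(P), tolerance = 1e-12)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(sum(ev < 1e-8 * max(ev)), 2)  # null space: constants + slope
  # a linear function has zero curvature energy
  x <- seq(0, 100, length.out = 200)
  cl <- qr.coef(qr(eval_basis(b, x)), 2 + 0.3 * x)
  expect_equal(drop(cl %*% P %*% cl), 0, tolerance = 1e-8)
})

test_that("spline coefficients solve ordinary least squares", {
  b <- bspline_basis(12)
  grid <- seq(0, 100, length.out = 101)
  B <- eval_basis(b, grid)
  # curve equal to one basis function -> unit coefficient vector
  for (j in c(1, 5, 12)) {
    co <- spline_coefficients(matrix(B[, j], 1), grid, b)
    expect_equal(drop(co), as.numeric(seq_len(12) == j), tolerance = 1e-10)
  }
  # constant curve -> all coefficients equal the constant
  co <- spline_coefficients(matrix(7, 1, 101), grid, b)
  expect_equal(drop(co), rep(7, 12), tolerance = 1e-10)
  # random curves match the normal-equations solution
  set.seed(4)
  Y <- matrix(rnorm(20 * 101), 20)
  got <- spline_coefficients(Y, grid, b)
  want <- t(solve(crossprod(B), crossprod(B, t(Y))))
  expect_equal(got, want, tolerance = 1e-8)
  expect_error(spline_coefficients(Y[, 1:8], grid[1:8], b),
               "rank deficient")
})

test_that("k-means separates planted blobs and relabels by size", {
  set.seed(10)
  blob1 <- matrix(rnorm(60 * 5), 60)          # larger cluster
  blob2 <- matrix(rnorm(20 * 5, mean = 30), 20)
  co <- rbind(blob1, blob2)
  cl <- cluster_curves(co, 2, seed = 3)
  truth <- rep(1:2, c(60, 20))
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1)
  expect_equal(cl$sizes, c(60, 20))           # cluster 1 is the largest
  expect_equal(unique(cl$assignments[1:60]), 1L)
  # duplicated rows land in the same cluster
  dup <- rbind(co, co[1, ], co[61, ])
  cld <- cluster_curves(dup, 2, seed = 3)
  expect_equal(cld$assignments[81], cld$assignments[1])
  expect_equal(cld$assignments[82], cld$assignments[61])
  expect_error(cluster_curves(co[1:3, ], 5), "fewer curves")
})

test_that("k equal to the number of points gives singleton clusters", {
  set.seed(11)
  co <- matrix(rnorm(6 * 3), 6) * 10
  cl <- cluster_curves(co, 6, seed = 1)
  expect_equal(sort(cl$sizes), rep(1L, 6))
  expect_equal(cl$inertia, 0, tolerance = 1e-10)
})

test_that("silhouette selection finds planted structure", {
  ac <- simulate_archetype_curves(400, seed = 21)
  b <- bspline_basis(12)
  co <- spline_coefficients(ac$values, ac$grid, b)
  ks <- select_k_silhouette(co, 2:6, seed = 2)
  expect_equal(ks$best_k, 4)
  expect_equal(nrow(ks$scores), 5)
  # two planted blobs
  set.seed(12)
  two <- rbind(matrix(rnorm(50 * 4), 50), matrix(rnorm(50 * 4, 25), 50))
  expect_equal(select_k_silhouette(two, 2:5, seed = 2)$best_k, 2)
})

test_that("stability ARI is 1 on well-separated clusters and label-invariant", {
  set.seed(13)
  co <- rbind(matrix(rnorm(40 * 4), 40), matrix(rnorm(40 * 4, 40), 40))
  st <- clustering_stability(co, 2, n_repeats = 5, base_seed = 7)
  expect_equal(st$mean_ari, 1)
  expect_equal(st$sd_ari, 0)
  # ARI invariance under label permutation
  a <- sample(1:3, 30, replace = TRUE)
  perm <- c(3, 1, 2)[a]
  expect_equal(mclust::adjustedRandIndex(a, perm), 1)
})

test_that("clustering is invariant to curve order up to labels", {
  ac <- simulate_archetype_curves(300, seed = 33)
  b <- bspline_basis(12)
  co <- spline_coefficients(ac$values, ac$grid, b)
  cl1 <- cluster_curves(co, 4, seed = 5)
  set.seed(99)
  perm <- sample(nrow(co))
  cl2 <- cluster_curves(co[perm, ], 4, seed = 5)
  expect_equal(mclust::adjustedRandIndex(cl1$assignments[perm],
                                         cl2$assignments), 1)
})

test_that("composition tables hold row-normalised cluster proportions", {
  set.seed(14)
  n <- 120
  assignments <- sample(1:3, n, replace = TRUE)
  cl <- structure(list(k = 3, assignments = assignments,
                       sizes = as.integer(table(assignments))),
                  class = "curve_clusters")
  meta <- data.frame(session_id = sample(c("training1", "training2"), n,
                                         replace = TRUE),
                     environment = sample(1:4, n, replace = TRUE),
                     is_first = rep(FALSE, n), is_last = rep(FALSE, n))
  meta$is_first[sample(n, 10)] <- TRUE
  meta$is_last[sample(which(!meta$is_first), 10)] <- TRUE
  tabs <- composition_tables(cl, meta)
  for (tab in tabs) {
    props <- as.matrix(tab[, grep("^cluster_", names(tab))])
    expect_equal(unname(rowSums(props)), rep(1, nrow(props)),
                 tolerance = 1e-12)
  }
  expect_error(composition_tables(cl, meta[, -2]), "environment")
  # degenerate: everything in one cluster
  cl1 <- structure(list(k = 2, assignments = rep(1L, n),
                        sizes = c(n, 0L)), class = "curve_clusters")
  t1 <- composition_tables(cl1, meta)
  expect_true(all(t1$by_session$cluster_1 == 1))
})
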