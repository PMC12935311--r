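#' Cubic B-spline basis with equally spaced knots
#'
#' A clamped B-spline basis of the given order (4 = cubic) on `range`, with
#' `n_basis - order + 2` equally spaced breakpoints. The basis functions form
#' a partition of unity on the interval.
#'
#' @param n_basis Number of basis functions (>= order).
#' @param range Numeric length-2 interval, default `c(0, 100)`.
#' @param order Spline order (degree + 1); 4 for cubic splines.
#' @return An object of class `"bspline_basis"`.
#' @examples
#' b <- bspline_basis(12)
#' rowSums(eval_basis(b, seq(0, 100, 5)))  # all 1: partition of unity
#' @export
bspline_basis <- function(n_basis, range = c(0, 100), order = 4L) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (n_basis < order)
    stop("n_basis must be at least the spline order (", order, ")",
         call. = FALSE)
  breaks <- seq(range[1], range[2], length.out = n_basis - order + 2L)
  knots <- c(rep(range[1], order - 1L), breaks, rep(range[2], order - 1L))
  structure(list(n_basis = n_basis, order = order, range = range,
                 breaks = breaks, knots = knots,
                 .cache = new.env(parent = emptyenv())),
            class = "bspline_basis")
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("B-spline basis: order ", x$order, ", ", x$n_basis,
      " functions on [", x$range[1], ", ", x$range[2], "], ",
      length(x$breaks) - 2L, " interior knots\n", sep = "")
  invisible(x)
}

#' Evaluate a B-spline basis (or a derivative) at given points
#'
#' @param basis A [bspline_basis()].
#' @param x Evaluation points inside the basis range.
#' @param deriv Derivative order (0 = the functions themselves).
#' @return `length(x) x n_basis` design matrix.
#' @export
eval_basis <- function(basis, x, deriv = 0L) {
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(x)))
}

#' Curvature (roughness) penalty matrix of a basis
#'
#' Computes `P[j, l] = integral of B_j''(t) B_l''(t) dt` exactly by
#' per-interval 3-point Gauss–Legendre quadrature (the integrand is piecewise
#' polynomial of degree at most `2 * (order - 3)` between knots).
#'
#' @param basis A [bspline_basis()].
#' @param deriv Derivative order to penalise (2 = curvature).
#' @return Symmetric positive semi-definite `n_basis x n_basis` matrix.
#' @export
basis_penalty <- function(basis, deriv = 2L) {
  key <- paste0("pen", deriv)
  if (!is.null(basis$.cache) && !is.null(basis$.cache[[key]]))
    return(basis$.cache[[key]])
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  P <- matrix(0, basis$n_basis, basis$n_basis)
  br <- basis$breaks
  for (i in seq_len(length(br) - 1L)) {
    h <- (br[i + 1] - br[i]) / 2
    mid <- (br[i + 1] + br[i]) / 2
    xs <- mid + h * gp
    B2 <- eval_basis(basis, xs, deriv = deriv)
    P <- P + h * crossprod(B2 * sqrt(gw), B2 * sqrt(gw))
  }
  P <- (P + t(P)) / 2
  if (!is.null(basis$.cache)) basis$.cache[[key]] <- P
  P
}

#' Least-squares B-spline coefficients of normalised curves
#'
#' `fit_spline_coefficients()` fits one curve; `spline_coefficients()` fits a
#' whole curve matrix sharing a grid with a single QR decomposition. The
#' solution is the ordinary least-squares projection of the curve values onto
#' the basis evaluated on the grid.
#'
#' @param curve A `"normalized_curve"`.
#' @param basis A [bspline_basis()] on the curve's grid range.
#' @return Numeric coefficient vector of length `n_basis`.
#' @export
fit_spline_coefficients <- function(curve, basis) {
  drop(spline_coefficients(matrix(curve$values, nrow = 1), curve$grid, basis))
}

#' @rdname fit_spline_coefficients
#' @param values Curves-by-grid numeric matrix.
#' @param grid Common evaluation grid.
#' @export
spline_coefficients <- function(values, grid, basis) {
  if (length(grid) < basis$n_basis)
    stop("grid has fewer points (", length(grid), ") than basis functions (",
         basis$n_basis, "): least-squares fit is rank deficient",
         call. = FALSE)
  B <- eval_basis(basis, grid)
  qrB <- qr(B)
  coefs <- t(qr.coef(qrB, t(values)))
  dimnames(coefs) <- NULL
  coefs
}

# Run a block of code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' K-means clustering of spline coefficient vectors
#'
#' Clusters curves in coefficient space with `stats::kmeans` (multiple random
#' restarts, best inertia kept). Cluster labels are relabelled by decreasing
#' cluster size, so cluster 1 is always the largest.
#'
#' @param coefs Curves-by-coefficients matrix (see [spline_coefficients()]).
#' @param k Number of clusters (>= 2, <= number of curves).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts.
#' @return An object of class `"curve_clusters"`: `k`, `centroids`
#'   (k x n_basis), `assignments`, `sizes`, `inertia` (total within-cluster
#'   sum of squares), `seed`.
#' @export
cluster_curves <- function(coefs, k, seed = 1L, nstart = 10L) {
  coefs <- as.matrix(coefs)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (nrow(coefs) < k)
    stop("fewer curves (", nrow(coefs), ") than clusters (", k, ")",
         call. = FALSE)
  if (k == nrow(coefs)) {
    # one point per cluster: exact, no iteration needed
    return(structure(list(k = k, centroids = coefs,
                          assignments = seq_len(k),
                          sizes = rep(1L, k), inertia = 0, seed = seed),
                     class = "curve_clusters"))
  }
  km <- with_seed(seed,
                  stats::kmeans(coefs, centers = k, nstart = nstart,
                                iter.max = 100L))
  ord <- order(km$size, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(k = k,
                 centroids = km$centers[ord, , drop = FALSE],
                 assignments = relabel[km$cluster],
                 sizes = km$size[ord],
                 inertia = km$tot.withinss,
                 seed = seed),
            class = "curve_clusters")
}

#' @export
print.curve_clusters <- function(x, ...) {
  cat("K-means curve clustering: k = ", x$k, ", sizes ",
      paste(x$sizes, collapse = "/"), " (",
      paste(sprintf("%.1f%%", 100 * x$sizes / sum(x$sizes)), collapse = "/"),
      "), inertia ", format(x$inertia, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Select the number of clusters by mean silhouette width
#'
#' Clusters at every K in `k_range` and scores each solution by the mean
#' silhouette width over curves; the K with the highest mean silhouette is
#' selected and the full score table is returned for elbow-style plots.
#'
#' @inheritParams cluster_curves
#' @param k_range Candidate cluster counts, a subset of `2..(n - 1)`.
#' @return List with `best_k` and `scores` (data frame `k`, `silhouette`).
#' @export
select_k_silhouette <- function(coefs, k_range = 2:8, seed = 1L,
                                nstart = 10L) {
  coefs <- as.matrix(coefs)
  if (any(k_range < 2) || any(k_range >= nrow(coefs)))
    stop("k_range must lie within 2..(number of curves - 1)", call. = FALSE)
  dd <- stats::dist(coefs)
  sil <- vapply(k_range, function(k) {
    cl <- cluster_curves(coefs, k, seed = seed, nstart = nstart)
    mean(cluster::silhouette(cl$assignments, dd)[, "sil_width"])
  }, numeric(1))
  list(best_k = k_range[which.max(sil)],
       scores = data.frame(k = k_range, silhouette = sil))
}

#' Seed-stability of a clustering via the adjusted Rand index
#'
#' Reclusters the same coefficients `n_repeats` times under different seeds
#' and compares each run to the reference clustering at `base_seed` with the
#' adjusted Rand index (1 = identical partitions up to label permutation).
#'
#' @inheritParams cluster_curves
#' @param n_repeats Number of reclustering runs (>= 2).
#' @param base_seed Seed of the reference clustering; repeat r uses seed
#'   `base_seed + r`.
#' @return List with `mean_ari`, `sd_ari`, `ari` (per-repeat values) and the
#'   `reference` clustering.
#' @export
clustering_stability <- function(coefs, k, n_repeats = 100L, base_seed = 1L,
                                 nstart = 10L) {
  if (n_repeats < 2) stop("n_repeats must be at least 2", call. = FALSE)
  ref <- cluster_curves(coefs, k, seed = base_seed, nstart = nstart)
  ari <- vapply(seq_len(n_repeats), function(r) {
    cl <- cluster_curves(coefs, k, seed = base_seed + r, nstart = nstart)
    mclust::adjustedRandIndex(ref$assignments, cl$assignments)
  }, numeric(1))
  list(mean_ari = mean(ari), sd_ari = stats::sd(ari), ari = ari,
       reference = ref)
}

#' Cluster composition tables
#'
#' Cross-tabulates cluster assignments against curve metadata: by training
#' session, by environment, and by segment position (all segments, first
#' segments — session start to first object — and final segments). Each row
#' holds cluster proportions and sums to 1.
#'
#' @param clusters A `"curve_clusters"` object.
#' @param meta Data frame with one row per clustered curve; must contain
#'   `session_id`, `environment`, `is_first`, `is_last`.
#' @return List of data frames `by_session`, `by_environment`, `by_position`.
#' @export
composition_tables <- function(clusters, meta) {
  need <- c("session_id", "environment", "is_first", "is_last")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("curve metadata missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != length(clusters$assignments))
    stop("metadata rows (", nrow(meta), ") do not match number of clustered ",
         "curves (", length(clusters$assignments), ")", call. = FALSE)
  a <- factor(clusters$assignments, levels = seq_len(clusters$k))
  prop_rows <- function(split_by) {
    tab <- table(split_by, a)
    sweep(tab, 1, rowSums(tab), "/")
  }
  as_df <- function(tab, label) {
    df <- as.data.frame.matrix(tab)
    names(df) <- paste0("cluster_", seq_len(clusters$k))
    cbind(stats::setNames(data.frame(rownames(tab)), label), df,
          row.names = NULL)
  }
  pos <- rep("all", nrow(meta))
  by_pos <- rbind(
    prop_rows(pos),
    prop_rows(ifelse(meta$is_first, "first", "other"))["first", , drop = FALSE],
    prop_rows(ifelse(meta$is_last, "final", "other"))["final", , drop = FALSE])
  rownames(by_pos) <- c("all", "first", "final")
  list(by_session = as_df(prop_rows(meta$session_id), "session"),
       by_environment = as_df(prop_rows(meta$environment), "environment"),
       by_position = as_df(by_pos, "position"))
}

#' Reconstruct centroid curves on a grid
#'
#' @param clusters A `"curve_clusters"`.
#' @param basis The [bspline_basis()] the coefficients were fitted with.
#' @param grid Evaluation grid.
#' @return k x length(grid) matrix of centroid curves.
#' @export
centroid_curves <- function(clusters, basis, grid) {
  clusters$centroids %*% t(eval_basis(basis, grid))
}
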