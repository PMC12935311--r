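#' Scalar-on-functional regression with a roughness penalty
#'
#' Fits the model
#' `y_i = z_i' gamma + integral X_i(t) beta(t) dt + e_i`,
#' where `z_i` are scalar covariates given by `formula`, `X_i(t)` is the
#' participant's functional covariate (a normalised cost-difference curve on
#' a common grid) and `beta(t)` is expanded on a cubic B-spline basis with
#' `n_basis` functions. Estimation is penalised least squares with a
#' curvature penalty `lambda * integral beta''(t)^2 dt`; the functional
#' integral is evaluated by trapezoidal quadrature on the grid (exact for
#' piecewise-linear curves). Standard errors of the scalar coefficients use
#' the effective-degrees-of-freedom sandwich approximation for the penalised
#' fit, and the reported p-values are therefore approximate.
#'
#' Rows with a missing outcome or covariate are dropped (with their curves).
#'
#' @param formula Scalar-part formula, e.g. `y1 ~ age + sex + skill`.
#' @param data Data frame of outcomes and scalar covariates, one row per
#'   participant.
#' @param curves Numeric matrix of functional covariates, one row per row of
#'   `data`, columns on `grid`.
#' @param grid Evaluation grid of the curves; defaults to `0..100` equally
#'   spaced over the columns of `curves`.
#' @param n_basis Number of B-spline basis functions for `beta(t)`.
#' @param lambda Smoothing parameter of the curvature penalty.
#' @param ridge Optional numerical stabilisation: a proportional ridge
#'   (`ridge * mean diag of the crossproduct`) added to the whole penalised
#'   system. Needed only when the functional covariates are rank-deficient
#'   (e.g. many identically-zero curves), which leaves the linear part of
#'   `beta(t)` — the curvature penalty's null space — unidentified. Default
#'   0 (pure penalised least squares).
#' @return An object of class `"sofr"`; see Details for components. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`, plus [sofr_bootstrap()] for confidence bands.
#' @details The fit object contains `gamma` (scalar coefficient table with
#'   SEs and approximate p-values), `beta_coeffs`, `beta` (the functional
#'   coefficient evaluated on `grid`), `lambda`, `r_squared`, `sigma2`,
#'   `edf`, `df_residual`, and the ingredients needed to refit under
#'   resampling.
#' @examples
#' set.seed(1)
#' d <- simulate_sofr_data(n = 80, seed = 1)
#' fit <- sofr(y ~ age + skill, d$data, d$curves, d$grid)
#' fit
#' @export
sofr <- function(formula, data, curves, grid = NULL, n_basis = 10,
                 lambda = 0.1, ridge = 0) {
  curves <- as.matrix(curves)
  if (nrow(curves) != nrow(data))
    stop("curves must have one row per row of data", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, 100, length.out = ncol(curves))
  if (length(grid) != ncol(curves))
    stop("grid length must match the number of curve columns", call. = FALSE)

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  ok <- stats::complete.cases(y, Z, curves)
  y <- y[ok]; Z <- Z[ok, , drop = FALSE]; X <- curves[ok, , drop = FALSE]
  n <- length(y)

  basis <- bspline_basis(n_basis, range = range(grid))
  B <- eval_basis(basis, grid)
  qw <- trapezoid_weights(grid)
  J <- X %*% (B * qw)                      # n x n_basis integral design
  fit <- sofr_solve(y, Z, J, basis, lambda, ridge)

  beta_grid <- drop(B %*% fit$beta_coeffs)
  structure(c(fit, list(
    call = match.call(), formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    grid = grid, basis = basis, lambda = lambda, ridge = ridge,
    n = n, dropped = sum(!ok),
    beta = beta_grid,
    y = y, Z = Z, J = J, curves = X)), class = "sofr")
}

trapezoid_weights <- function(grid) {
  g <- as.numeric(grid)
  n <- length(g)
  w <- numeric(n)
  w[1] <- (g[2] - g[1]) / 2
  w[n] <- (g[n] - g[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / 2
  w
}

# Penalised least-squares core shared by sofr() and the bootstrap.
sofr_solve <- function(y, Z, J, basis, lambda, ridge = 0) {
  pz <- ncol(Z); nb <- basis$n_basis
  D <- cbind(Z, J)
  P <- matrix(0, pz + nb, pz + nb)
  bi <- pz + seq_len(nb)
  P[bi, bi] <- lambda * basis_penalty(basis)
  if (all(J == 0))
    # no functional information at all: pin beta at 0 so the fit reduces
    # to ordinary least squares on the scalar covariates
    P[bi, bi] <- P[bi, bi] + diag(nb)
  M <- crossprod(D) + P
  if (ridge > 0) M <- M + ridge * mean(diag(crossprod(D))) * diag(pz + nb)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[length(ev)] <= 1e-13 * ev[1])
    stop("singular penalised design; increase lambda or reduce n_basis",
         call. = FALSE)
  Minv <- chol2inv(chol(M))
  est <- drop(Minv %*% crossprod(D, y))
  fitted <- drop(D %*% est)
  res <- y - fitted
  rss <- sum(res^2)
  DtD <- crossprod(D)
  edf <- sum(diag(Minv %*% DtD))
  n <- length(y)
  df_residual <- n - edf
  sigma2 <- rss / df_residual
  covm <- sigma2 * Minv %*% DtD %*% Minv
  se <- sqrt(pmax(diag(covm), 0))
  gi <- seq_len(pz)
  tval <- est[gi] / se[gi]
  gamma <- data.frame(term = colnames(Z),
                      estimate = est[gi], se = se[gi], t = tval,
                      p_value = 2 * stats::pt(-abs(tval), df = df_residual))
  rownames(gamma) <- NULL
  tss <- sum((y - mean(y))^2)
  list(gamma = gamma,
       beta_coeffs = est[pz + seq_len(nb)],
       beta_coef_se = se[pz + seq_len(nb)],
       coefficients = stats::setNames(est, c(colnames(Z),
                                             paste0("beta_", seq_len(nb)))),
       cov = covm, fitted_values = fitted, residuals = res,
       sigma2 = sigma2, edf = edf, df_residual = df_residual,
       r_squared = 1 - rss / tss, rss = rss)
}

#' @export
print.sofr <- function(x, digits = 4, ...) {
  cat("Scalar-on-functional regression (penalised least squares)\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  est <- x$gamma$estimate
  names(est) <- x$gamma$term
  print(round(est, digits))
  cat("\nFunctional coefficient: ", x$basis$n_basis,
      " B-spline basis functions, lambda = ", x$lambda,
      "; R-squared ", round(x$r_squared, digits), " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.sofr <- function(object, ...) {
  structure(list(call = object$call, gamma = object$gamma,
                 lambda = object$lambda, n_basis = object$basis$n_basis,
                 r_squared = object$r_squared, sigma2 = object$sigma2,
                 edf = object$edf, n = object$n, dropped = object$dropped,
                 has_bootstrap = !is.null(object$bootstrap)),
            class = "summary.sofr")
}

#' @export
print.summary.sofr <- function(x, digits = 4, ...) {
  cat("Scalar-on-functional regression\nCall: ", deparse(x$call), "\n\n",
      sep = "")
  tab <- x$gamma
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  cat("\n(p-values from the effective-df sandwich approximation ",
      "to the penalised fit; approximate)\n", sep = "")
  cat("beta(t): ", x$n_basis, " basis functions, lambda = ", x$lambda,
      ", effective df ", round(x$edf, 2), "\n", sep = "")
  cat("n = ", x$n, if (x$dropped) paste0(" (", x$dropped,
                                         " incomplete rows dropped)"),
      ", R-squared = ", round(x$r_squared, digits),
      ", residual variance = ", signif(x$sigma2, digits), "\n", sep = "")
  if (x$has_bootstrap) cat("Bootstrap 95% bands available; see plot().\n")
  invisible(x)
}

#' @export
coef.sofr <- function(object, ...) object$coefficients

#' @export
fitted.sofr <- function(object, ...) object$fitted_values

#' @export
residuals.sofr <- function(object, ...) object$residuals

#' Evaluate the fitted functional coefficient
#'
#' @param object A fitted `"sofr"` model.
#' @param grid Evaluation points (defaults to the fitting grid).
#' @return Numeric vector `beta(grid)`.
#' @export
eval_beta <- function(object, grid = object$grid) {
  drop(eval_basis(object$basis, grid) %*% object$beta_coeffs)
}

#' @export
predict.sofr <- function(object, newdata = NULL, newcurves = NULL, ...) {
  if (is.null(newdata) && is.null(newcurves)) return(object$fitted_values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass,
                           xlev = object$xlevels)
  Z <- stats::model.matrix(tt, mf)
  newcurves <- as.matrix(newcurves)
  if (nrow(newcurves) != nrow(Z))
    stop("newcurves must have one row per row of newdata", call. = FALSE)
  B <- eval_basis(object$basis, object$grid)
  J <- newcurves %*% (B * trapezoid_weights(object$grid))
  drop(cbind(Z, J) %*% object$coefficients)
}

#' @export
simulate.sofr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = sqrt(object$sigma2))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.sofr <- function(x, ...) {
  b <- x$beta
  lo <- x$bootstrap$beta_lower; hi <- x$bootstrap$beta_upper
  ylim <- range(c(b, lo, hi, 0), finite = TRUE)
  graphics::plot(x$grid, b, type = "l", lwd = 2, ylim = ylim,
                 xlab = "rescaled segment time", ylab = expression(beta(t)),
                 main = "Functional coefficient", ...)
  if (!is.null(lo)) {
    graphics::lines(x$grid, lo, lty = 2)
    graphics::lines(x$grid, hi, lty = 2)
  }
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Bootstrap confidence bands for the functional coefficient
#'
#' Case-resampling bootstrap over participants: each replicate refits the
#' penalised model on a resample of rows and re-evaluates `beta(t)` on the
#' fitting grid; pointwise 2.5% and 97.5% percentiles form the 95% band.
#' Replicates with a singular penalised design are redrawn (and counted).
#'
#' @param object A fitted `"sofr"` model.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended).
#' @param seed RNG seed.
#' @param level Band coverage level (default 0.95).
#' @return The fit with a `bootstrap` component: `n_boot`, `beta_lower`,
#'   `beta_upper`, `beta_draws` (n_boot x grid), `gamma_se_boot`,
#'   `singular_redraws`.
#' @export
sofr_bootstrap <- function(object, n_boot = 200, seed = 1L, level = 0.95) {
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  n <- object$n
  B <- eval_basis(object$basis, object$grid)
  pz <- ncol(object$Z)
  draws <- matrix(NA_real_, n_boot, length(object$grid))
  gdraws <- matrix(NA_real_, n_boot, pz)
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- tryCatch(
          sofr_solve(object$y[idx], object$Z[idx, , drop = FALSE],
                     object$J[idx, , drop = FALSE], object$basis,
                     object$lambda, object$ridge %||% 0),
          error = function(e) NULL)
        if (!is.null(fit)) break
        redraws <- redraws + 1L
        if (redraws > 50L * n_boot)
          stop("bootstrap failed: too many singular replicates", call. = FALSE)
      }
      draws[r, ] <- drop(B %*% fit$beta_coeffs)
      gdraws[r, ] <- fit$gamma$estimate
    }
  })
  alpha <- (1 - level) / 2
  object$bootstrap <- list(
    n_boot = n_boot, level = level,
    beta_lower = apply(draws, 2, stats::quantile, probs = alpha),
    beta_upper = apply(draws, 2, stats::quantile, probs = 1 - alpha),
    beta_draws = draws,
    gamma_se_boot = apply(gdraws, 2, stats::sd),
    singular_redraws = redraws)
  object
}
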