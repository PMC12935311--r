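test_that("with zero functional covariates the fit reduces to lm", {
  set.seed(20)
  n <- 60
  d <- data.frame(age = runif(n, 18, 40),
                  skill = factor(sample(c("Expert", "Novice"), n, TRUE)))
  d$y <- 1 + 0.1 * d$age - 2 * (d$skill == "Novice") + rnorm(n)
  X0 <- matrix(0, n, 101)
  fit <- sofr(y ~ age + skill, d, X0)
  ref <- lm(y ~ age + skill, d)
  expect_equal(fit$gamma$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-6)
  # beta is fully shrunk toward the penalty null space and irrelevant
  expect_equal(unname(predict(fit, d, X0)), unname(fitted(ref)),
               tolerance = 1e-8)
})

test_that("noiseless scalar-only data are recovered exactly", {
  set.seed(21)
  n <- 50
  d <- data.frame(age = runif(n, 18, 40),
                  skill = factor(sample(c("Expert", "Intermediate",
                                          "Novice"), n, TRUE)))
  gamma <- c(2, 0.05, -1, -1.5)
  Z <- model.matrix(~ age + skill, d)
  d$y <- drop(Z %*% gamma)                 # sigma = 0, beta = 0
  fit <- sofr(y ~ age + skill, d, matrix(0, n, 101))
  expect_equal(fit$gamma$estimate, gamma, tolerance = 1e-8)
  expect_equal(max(abs(fit$beta)), 0, tolerance = 1e-6)
})

test_that("the penalised solution minimises the stated objective", {
  # independent check by general-purpose numerical optimisation
  d <- simulate_sofr_data(n = 40, grid = seq(0, 100, length.out = 21),
                          seed = 5)
  fit <- sofr(y ~ age + skill, d$data, d$curves, d$grid, n_basis = 6,
              lambda = 0.3)
  b <- bspline_basis(6, range = range(d$grid))
  B <- eval_basis(b, d$grid)
  qw <- diff(d$grid)[1] * c(0.5, rep(1, 19), 0.5)
  Z <- model.matrix(~ age + skill, d$data)
  P <- basis_penalty(b)
  obj <- function(th) {
    g <- th[1:4]; bc <- th[5:10]
    sum((d$data$y - Z %*% g - d$curves %*% (B * qw) %*% bc)^2) +
      0.3 * drop(bc %*% P %*% bc)
  }
  opt <- optim(rep(0, 10), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_lte(obj(unname(coef(fit))), opt$value + 1e-6)
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-3)
})

test_that("increasing lambda never increases the fitted roughness", {
  d <- simulate_sofr_data(n = 150, seed = 6)
  b <- bspline_basis(10, range = range(d$grid))
  P <- basis_penalty(b)
  rough <- vapply(c(0.001, 0.1, 10, 1000, 1e5), function(l) {
    f <- sofr(y ~ age + skill, d$data, d$curves, d$grid, lambda = l)
    drop(f$beta_coeffs %*% P %*% f$beta_coeffs)
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-8 * max(rough)))
})

test_that("prediction, residuals and simulate are mutually consistent", {
  d <- simulate_sofr_data(n = 100, seed = 7)
  fit <- sofr(y ~ age + skill, d$data, d$curves, d$grid)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(unname(fitted(fit) + residuals(fit)), d$data$y)
  expect_equal(unname(predict(fit, d$data, d$curves)), unname(fitted(fit)),
               tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(100L, 3L))
  expect_gt(cor(sims$sim_1, fitted(fit)), 0.9)
  s <- summary(fit)
  expect_s3_class(s, "summary.sofr")
  expect_output(print(s), "R-squared")
})

test_that("rows with missing outcomes are dropped with their curves", {
  d <- simulate_sofr_data(n = 80, seed = 8)
  d$data$y[c(3, 17)] <- NA
  fit <- sofr(y ~ age + skill, d$data, d$curves, d$grid)
  expect_equal(fit$n, 78)
  expect_equal(fit$dropped, 2)
})

test_that("bootstrap bands are ordered, centred and shrink without noise", {
  d <- simulate_sofr_data(n = 120, sigma = 2, seed = 9)
  fit <- sofr_bootstrap(sofr(y ~ age + skill, d$data, d$curves, d$grid),
                        n_boot = 120, seed = 2)
  bb <- fit$bootstrap
  expect_true(all(bb$beta_lower <= bb$beta_upper))
  expect_true(mean(bb$beta_lower <= fit$beta &
                     fit$beta <= bb$beta_upper) > 0.9)
  d0 <- simulate_sofr_data(n = 120, sigma = 0.01, seed = 9)
  fit0 <- sofr_bootstrap(sofr(y ~ age + skill, d0$data, d0$curves, d0$grid),
                         n_boot = 120, seed = 2)
  expect_lt(mean(fit0$bootstrap$beta_upper - fit0$bootstrap$beta_lower),
            mean(bb$beta_upper - bb$beta_lower))
  # plot method runs silently on a null device
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("degenerate functional designs error, and ridge stabilises them", {
  set.seed(30)
  n <- 12
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  X <- outer(rnorm(n), sin(seq(0, pi, length.out = 101)))  # rank 1
  expect_error(sofr(y ~ x, d, X), "singular")
  fit <- sofr(y ~ x, d, X, ridge = 1e-6)
  expect_s3_class(fit, "sofr")
  expect_true(all(is.finite(coef(fit))))
})
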