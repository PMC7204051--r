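test_that("log-jacobian matches closed forms and dense determinants", {
  expect_equal(log_jacobian(0, c(1, -0.5, 0.2)), 0)
  # two mutually adjacent tracts: spectrum {1, -1}
  pair <- row_standardize(tract_adjacency(c("a", "b"), list(a = "b", b = "a")))
  ev <- weights_eigenvalues(pair)
  expect_equal(sort(ev), c(-1, 1))
  expect_equal(log_jacobian(0.5, ev), log(0.75))
  # dense-factorization oracle on grids
  for (dims in list(c(3, 3), c(5, 5), c(10, 10))) {
    lat <- lattice_weights(dims[1], dims[2])
    Wd <- as.matrix(lat$w$W)
    for (lam in c(-0.5, 0, 0.4, 0.9)) {
      expect_equal(log_jacobian(lam, lat$ev),
                   as.numeric(determinant(diag(nrow(Wd)) - lam * Wd,
                                          logarithm = TRUE)$modulus),
                   tolerance = 1e-8)
    }
  }
  expect_error(log_jacobian(1.5, c(1, -0.5)), "admissible")
})

test_that("profile likelihood at lambda 0 is the OLS concentrated likelihood", {
  lat <- lattice_weights(5, 5)
  set.seed(11)
  X <- simulate_covariates(lat$w, 2, rho = 0, seed = 11)
  y <- rnorm(25)
  Z <- build_design(X, lat$w, include_lagged = FALSE)
  ll <- profile_loglik(0, y, Z, lat$w, eigenvalues = lat$ev)
  expect_equal(ll, as.numeric(logLik(lm(y ~ X))), tolerance = 1e-10)
})

test_that("a perfect fit returns the +Inf guard", {
  lat <- lattice_weights(4, 4)
  X <- simulate_covariates(lat$w, 1, rho = 0, seed = 3)
  Z <- build_design(X, lat$w, include_lagged = FALSE)
  y <- as.numeric(Z %*% c(2, 0.5))
  expect_equal(profile_loglik(0, y, Z, lat$w, eigenvalues = lat$ev), Inf)
})

test_that("optimized lambda matches a brute-force refined grid search", {
  lat <- lattice_weights(5, 5)
  X <- simulate_covariates(lat$w, 2, rho = 0.4, seed = 21)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(1, -0.5), theta = c(0.3, 0),
                             lambda = 0.4, sigma = 1, seed = 22)
  fit <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  Z <- build_design(X, lat$w)
  lo <- 1 / min(lat$ev) + 1e-6; hi <- 1 - 1e-6
  prof <- function(l) profile_loglik(l, y, Z, lat$w, eigenvalues = lat$ev)
  grid1 <- seq(lo, hi, by = 1e-3)
  l1 <- grid1[which.max(vapply(grid1, prof, numeric(1)))]
  grid2 <- seq(max(lo, l1 - 2e-3), min(hi, l1 + 2e-3), by = 1e-6)
  l2 <- grid2[which.max(vapply(grid2, prof, numeric(1)))]
  expect_equal(fit$lambda, l2, tolerance = 1e-4)
})

test_that("profile maximum dominates a 200-point admissible grid", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 31)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(0.7, -0.2), theta = c(0.2, 0.1),
                             lambda = 0.3, sigma = 1, seed = 32)
  fit <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  Z <- build_design(X, lat$w)
  lo <- 1 / min(lat$ev) + 1e-4; hi <- 1 - 1e-4
  grid <- seq(lo, hi, length.out = 200)
  lls <- vapply(grid, function(l)
    profile_loglik(l, y, Z, lat$w, eigenvalues = lat$ev), numeric(1))
  expect_true(all(fit$loglik >= lls - 1e-8))
})

test_that("with lambda fixed at zero and no lag block the fit is OLS", {
  lat <- lattice_weights(5, 5)
  X <- simulate_covariates(lat$w, 3, rho = 0, seed = 41)
  set.seed(42)
  y <- 80 + X %*% c(1, -2, 0.5) + rnorm(25)
  fit <- fit_sdem(y, X, lat$w, include_lagged = FALSE, lambda = 0,
                  eigenvalues = lat$ev)
  Z <- cbind(1, X)
  closed_form <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(unname(fit$coefficients$estimate),
               unname(as.numeric(closed_form)), tolerance = 1e-8)
  expect_equal(fit$lambda, 0)
})

test_that("rank deficiency is reported with the collinear columns", {
  lat <- lattice_weights(5, 5)
  X <- cbind(simulate_covariates(lat$w, 1, rho = 0, seed = 51),
             const = 1)  # Wc = c, collinear with the transformed intercept
  y <- rnorm(25)
  expect_error(fit_sdem(y, X, lat$w, eigenvalues = lat$ev),
               "rank deficient")
})

test_that("estimates are equivariant to outcome translation", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 61)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(1, -0.5), theta = c(0.3, 0),
                             lambda = 0.4, sigma = 1, seed = 62)
  f1 <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  f2 <- fit_sdem(y + 100, X, lat$w, eigenvalues = lat$ev)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-8)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-8)
  expect_equal(f2$fitted_trend, f1$fitted_trend + 100, tolerance = 1e-7)
})

test_that("coefficients rescale inversely to covariate scaling", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 71)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(1, -0.5), theta = c(0.3, 0),
                             lambda = 0.4, sigma = 1, seed = 72)
  X10 <- X; X10[, 1] <- X10[, 1] * 10
  f1 <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  f2 <- fit_sdem(y, X10, lat$w, eigenvalues = lat$ev)
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]) / 10, tolerance = 1e-8)
  expect_equal(unname(f2$theta[1]), unname(f1$theta[1]) / 10,
               tolerance = 1e-8)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("AIC identity holds exactly and counts k + 2 parameters", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 81)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(1, -0.5), theta = c(0.3, 0),
                             lambda = 0.4, sigma = 1, seed = 82)
  fit <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  expect_identical(fit$npar, fit$k + 2L)
  expect_identical(fit$aic, 2 * fit$npar - 2 * fit$loglik)
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
  expect_gt(fit$sigma2, 0)
})

test_that("design matrix blocks are labeled and sized correctly", {
  lat <- lattice_weights(4, 4)
  X <- simulate_covariates(lat$w, 3, rho = 0, seed = 91)
  Z1 <- build_design(X, lat$w, include_lagged = TRUE)
  expect_equal(ncol(Z1), 1 + 2 * 3)
  expect_equal(attr(Z1, "block"),
               c("intercept", rep("direct", 3), rep("lag", 3)))
  Z0 <- build_design(X, lat$w, include_lagged = FALSE)
  expect_equal(ncol(Z0), 1 + 3)
  Xbad <- X; Xbad[2, 1] <- NA
  expect_error(build_design(Xbad, lat$w), "x1")
})

test_that("impacts decompose into direct, indirect and their exact sum", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 101)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(0.13, -0.5),
                             theta = c(0.06, 0), lambda = 0.4, sigma = 0.5,
                             seed = 102)
  fit <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  imp <- impacts(fit)
  expect_identical(imp$total, imp$direct + imp$indirect)
  expect_false("total_p" %in% names(imp))
  expect_equal(unname(imp$direct), unname(fit$beta))
  expect_equal(unname(imp$indirect), unname(fit$theta))
  fit0 <- fit_sdem(y, X, lat$w, include_lagged = FALSE,
                   eigenvalues = lat$ev)
  expect_error(impacts(fit0), "lag")
})

test_that("likelihood ratio test behaves at its boundaries", {
  lat <- lattice_weights(6, 6)
  X <- simulate_covariates(lat$w, 2, rho = 0.5, seed = 111)
  y <- simulate_sdem_outcome(X, lat$w, beta = c(1, -0.5), theta = c(0.8, 0.8),
                             lambda = 0.4, sigma = 1, seed = 112)
  full <- fit_sdem(y, X, lat$w, eigenvalues = lat$ev)
  nested <- fit_sdem(y, X, lat$w, include_lagged = FALSE,
                     eigenvalues = lat$ev)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lr <- lr_test(full, nested)
  expect_equal(lr$df, 2)
  expect_gte(lr$statistic, 0)
  # non-nested: nested fit has a column the full fit lacks
  other <- fit_sdem(y, X[, 1, drop = FALSE], lat$w,
                    eigenvalues = lat$ev)
  expect_error(lr_test(other, nested), "not nested")
})
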