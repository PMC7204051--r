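#' Design matrix for the spatial Durbin error model
#'
#' Assembles \eqn{Z = [1, X, WX]}: an intercept, the covariates, and (when
#' \code{include_lagged}) their spatial lags. Lag columns are labeled
#' \code{lag.<name>} and the block of each column (\code{intercept},
#' \code{direct}, \code{lag}) is stored as an attribute, so impact
#' decompositions can tell local from neighbor effects.
#'
#' @param X Numeric matrix or data frame of covariates, rows aligned to
#'   \code{w$ids}.
#' @param w Row-standardized \code{\link{spatial_weights}}.
#' @param include_lagged Add the \eqn{WX} block (default TRUE).
#' @return Numeric matrix with attribute \code{"block"}.
#' @export
build_design <- function(X, w, include_lagged = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(w$ids))
    stop("covariate rows must align with the weights ids", call. = FALSE)
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite covariate value in column '", colnames(X)[bad[2]],
         "', tract ", w$ids[bad[1]], call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = 1, X)
  block <- c("intercept", rep("direct", ncol(X)))
  if (include_lagged) {
    WX <- spatial_lag(w, X)
    colnames(WX) <- paste0("lag.", colnames(X))
    Z <- cbind(Z, WX)
    block <- c(block, rep("lag", ncol(X)))
  }
  attr(Z, "block") <- block
  Z
}

#' Log-determinant of I - lambda*W from eigenvalues
#'
#' The Jacobian term of the spatial-error likelihood,
#' \eqn{\ln|I - \lambda W| = \sum_i \ln(1 - \lambda \omega_i)}, valid while
#' \eqn{1 - \lambda\omega_i > 0} for every eigenvalue.
#'
#' @param lambda Spatial autocorrelation parameter.
#' @param eigenvalues Spectrum of W (see \code{\link{weights_eigenvalues}}).
#' @return The log-determinant (scalar).
#' @export
log_jacobian <- function(lambda, eigenvalues) {
  z <- 1 - lambda * eigenvalues
  if (any(z <= 0))
    stop("lambda = ", lambda, " outside the admissible interval of W",
         call. = FALSE)
  sum(log(z))
}

.sdem_precompute <- function(y, Z, w, eigenvalues = NULL) {
  list(
    y = as.numeric(y), Z = Z,
    Wy = as.numeric(w$W %*% y),
    WZ = as.matrix(w$W %*% Z),
    ev = if (is.null(eigenvalues)) weights_eigenvalues(w) else eigenvalues,
    n = length(y)
  )
}

.profile_core <- function(lambda, pc) {
  Ay <- pc$y - lambda * pc$Wy
  AZ <- pc$Z - lambda * pc$WZ
  qrz <- qr(AZ)
  if (qrz$rank < ncol(AZ)) {
    drop <- colnames(pc$Z)[qrz$pivot[(qrz$rank + 1):ncol(AZ)]]
    stop("design matrix is rank deficient after spatial transform; ",
         "collinear column(s): ", paste(drop, collapse = ", "),
         call. = FALSE)
  }
  gamma <- qr.coef(qrz, Ay)
  res <- Ay - AZ %*% gamma
  rss <- sum(res^2)
  list(gamma = gamma, rss = rss, AZ = AZ, resid = as.numeric(res))
}

#' Concentrated (profile) log-likelihood of the spatial error model
#'
#' For a candidate \eqn{\lambda}, transforms the data by
#' \eqn{A = I - \lambda W}, estimates the regression coefficients by least
#' squares of \eqn{Ay} on \eqn{AZ}, concentrates out
#' \eqn{\sigma^2 = RSS/n}, and returns
#' \deqn{\ell(\lambda) = -\frac{n}{2}(\ln 2\pi + 1 + \ln\hat\sigma^2) + \ln|A|.}
#' A perfect fit (\eqn{RSS = 0}) returns \code{+Inf} as a guard rather than
#' overflowing.
#'
#' @param lambda Candidate spatial autocorrelation of the error process.
#' @param y Outcome vector.
#' @param Z Design matrix (see \code{\link{build_design}}).
#' @param w Row-standardized \code{\link{spatial_weights}}.
#' @param eigenvalues Optional precomputed spectrum of W.
#' @return Scalar log-likelihood.
#' @export
profile_loglik <- function(lambda, y, Z, w, eigenvalues = NULL) {
  pc <- .sdem_precompute(y, Z, w, eigenvalues)
  .profile_loglik_pc(lambda, pc)
}

.profile_loglik_pc <- function(lambda, pc) {
  ld <- log_jacobian(lambda, pc$ev)
  core <- .profile_core(lambda, pc)
  n <- pc$n
  s2 <- core$rss / n
  if (s2 <= max(1e-300, 1e-18 * stats::var(pc$y))) return(Inf)
  -(n / 2) * (log(2 * pi) + 1 + log(s2)) + ld
}

#' Fit the spatial Durbin error model by maximum likelihood
#'
#' Fits \deqn{y = \alpha + X\beta + WX\theta + u, \qquad u = \lambda W u +
#' \varepsilon, \quad \varepsilon \sim N(0, \sigma^2 I)} by concentrated
#' maximum likelihood: \eqn{\lambda} is found by bounded one-dimensional
#' optimization of \code{\link{profile_loglik}} over the admissible interval
#' \eqn{(1/\omega_{min}, 1)} of the row-standardized W, then the
#' coefficients, \eqn{\sigma^2}, and their covariance
#' \eqn{\hat\sigma^2 [(AZ)'AZ]^{-1}} are evaluated at \eqn{\hat\lambda}
#' (standard errors conditional on \eqn{\hat\lambda}; the \eqn{\lambda}
#' standard error comes from the numerical curvature of the profile).
#' Omitting the lag block (\code{include_lagged = FALSE}) fits the plain
#' spatial error model; fixing \code{lambda = 0} with no lag block reduces
#' to ordinary least squares.
#'
#' @param y Outcome per tract (years of life expectancy), aligned to
#'   \code{w$ids}.
#' @param X Covariate matrix or data frame, aligned to \code{w$ids}.
#' @param w Row-standardized, island-free \code{\link{spatial_weights}}
#'   (drop islands upstream).
#' @param include_lagged Include the \eqn{WX} block (default TRUE; the
#'   "Durbin" part).
#' @param lambda Fix \eqn{\lambda} at this value instead of estimating it
#'   (NULL = estimate).
#' @param eigenvalues Optional precomputed spectrum of W (reused across fits
#'   on the same lattice).
#' @param tol Optimizer tolerance (default 1e-10).
#' @return Object of class \code{"sdem_fit"}: coefficient table
#'   (\code{coefficients}: name, block, estimate, se, z, p), \code{alpha},
#'   \code{beta}, \code{theta}, \code{lambda}, \code{lambda_se},
#'   \code{sigma2}, \code{loglik}, \code{aic}, \code{npar}, \code{n},
#'   \code{k}, \code{r_squared}, \code{fitted_trend} (\eqn{Z\hat\gamma}),
#'   \code{residuals} (whitened innovations
#'   \eqn{\hat\varepsilon = (I-\hat\lambda W)(y - Z\hat\gamma)}), and
#'   \code{trend_residuals} (\eqn{y - Z\hat\gamma}).
#' @export
fit_sdem <- function(y, X, w, include_lagged = TRUE, lambda = NULL,
                     eigenvalues = NULL, tol = 1e-10) {
  stopifnot(inherits(w, "spatial_weights"))
  y <- as.numeric(y)
  if (length(y) != length(w$ids))
    stop("'y' must have one value per tract", call. = FALSE)
  if (any(!is.finite(y))) stop("'y' must be finite", call. = FALSE)
  if (length(w$islands))
    warning("weights contain ", length(w$islands),
            " island(s); estimates treat their rows as zero", call. = FALSE)

  Z <- build_design(X, w, include_lagged)
  k <- ncol(Z)
  n <- length(y)
  if (n < k + 2) stop("need n >= k + 2 observations", call. = FALSE)
  pc <- .sdem_precompute(y, Z, w, eigenvalues)

  ev_min <- min(pc$ev)
  lo <- if (ev_min < 0) 1 / ev_min + 1e-6 else -1 + 1e-6
  hi <- 1 - 1e-6

  lambda_fixed <- !is.null(lambda)
  if (lambda_fixed) {
    lam_hat <- lambda
    if (lam_hat != 0) log_jacobian(lam_hat, pc$ev)  # admissibility check
  } else {
    opt <- stats::optimize(function(l) .profile_loglik_pc(l, pc),
                           interval = c(lo, hi), maximum = TRUE, tol = tol)
    lam_hat <- opt$maximum
    # polish with parabolic-vertex steps at a fixed spacing: the wide
    # stencil averages out the floating-point noise that limits golden
    # search near the flat top of the profile
    for (it in 1:2) {
      h <- min(1e-3, (lam_hat - lo) / 2, (hi - lam_hat) / 2)
      if (h <= 0) break
      f0 <- .profile_loglik_pc(lam_hat, pc)
      f1 <- .profile_loglik_pc(lam_hat - h, pc)
      f2 <- .profile_loglik_pc(lam_hat + h, pc)
      den <- f1 - 2 * f0 + f2
      if (!is.finite(den) || den >= 0) break
      step <- 0.5 * h * (f1 - f2) / den
      if (!is.finite(step) || abs(step) > h) break
      lam_hat <- lam_hat + step
    }
    if (lam_hat - lo < 1e-4 || hi - lam_hat < 1e-4)
      warning("lambda estimate at the boundary of the admissible interval (",
              signif(lam_hat, 6), "); profile maximum may not be interior",
              call. = FALSE)
  }

  core <- .profile_core(lam_hat, pc)
  sigma2 <- core$rss / n
  loglik <- if (lambda_fixed && lam_hat == 0)
    -(n / 2) * (log(2 * pi) + 1 + log(sigma2))
  else .profile_loglik_pc(lam_hat, pc)

  vcov_g <- sigma2 * chol2inv(chol(crossprod(core$AZ)))
  se <- sqrt(diag(vcov_g))
  est <- as.numeric(core$gamma)
  zstat <- est / se
  pval <- 2 * stats::pnorm(-abs(zstat))

  lambda_se <- NA_real_
  if (!lambda_fixed) {
    h <- max(1e-5, 1e-4 * (hi - lo))
    l1 <- max(lo, lam_hat - h); l2 <- min(hi, lam_hat + h)
    f0 <- .profile_loglik_pc(lam_hat, pc)
    f1 <- .profile_loglik_pc(l1, pc)
    f2 <- .profile_loglik_pc(l2, pc)
    d2 <- (f1 - 2 * f0 + f2) / ((l2 - lam_hat) * (lam_hat - l1))
    if (is.finite(d2) && d2 < 0) lambda_se <- sqrt(-1 / d2)
  }

  block <- attr(Z, "block")
  coefs <- data.frame(
    name = colnames(Z), block = block,
    estimate = est, se = se, z = zstat, p = pval,
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL

  fitted_trend <- as.numeric(Z %*% core$gamma)
  u <- y - fitted_trend
  eps <- as.numeric(u - lam_hat * (w$W %*% u))

  npar <- k + 1L + as.integer(!lambda_fixed)
  fit <- structure(list(
    coefficients = coefs,
    alpha = est[block == "intercept"],
    beta = stats::setNames(est[block == "direct"],
                           coefs$name[block == "direct"]),
    theta = if (include_lagged)
      stats::setNames(est[block == "lag"], coefs$name[block == "lag"])
    else NULL,
    lambda = lam_hat, lambda_se = lambda_se, lambda_fixed = lambda_fixed,
    sigma2 = sigma2, vcov = vcov_g,
    loglik = loglik, npar = npar, aic = 2 * npar - 2 * loglik,
    n = n, k = k, include_lagged = include_lagged,
    r_squared = stats::cor(y, fitted_trend)^2,
    fitted_trend = fitted_trend, trend_residuals = u, residuals = eps,
    y = y, Z = Z, eigenvalues = pc$ev
  ), class = "sdem_fit")
  fit
}

#' Significance stars
#'
#' Star codes at the conventional inclusive thresholds: \code{***} for
#' p <= 0.001, \code{**} for p <= 0.01, \code{*} for p <= 0.05.
#'
#' @param p Numeric p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' @export
print.sdem_fit <- function(x, ...) {
  cat("Spatial Durbin error model",
      if (!x$include_lagged) "(no lag block: spatial error model)", "\n")
  cat(sprintf("n = %d, k = %d, lambda = %.4f%s, sigma2 = %.4f\n",
              x$n, x$k, x$lambda, if (x$lambda_fixed) " (fixed)" else "",
              x$sigma2))
  cat(sprintf("logLik = %.3f, AIC = %.3f, pseudo-R2 = %.3f\n",
              x$loglik, x$aic, x$r_squared))
  tab <- x$coefficients
  tab$stars <- significance_stars(tab$p)
  print(tab, digits = 4)
  invisible(x)
}

#' Direct, indirect and total impacts
#'
#' In the spatial Durbin error model the spatial multiplier applies only to
#' the disturbance, so impacts are local: the direct effect of a covariate is
#' its own coefficient \eqn{\beta_k}, the indirect (neighbor) effect is the
#' lag coefficient \eqn{\theta_k}, and the total is their sum. The total
#' carries no significance measure.
#'
#' @param fit A converged \code{\link{fit_sdem}} with the lag block included.
#' @return Data frame: \code{name}, \code{direct}, \code{indirect},
#'   \code{total}, \code{direct_p}, \code{indirect_p}.
#' @export
impacts <- function(fit) {
  stopifnot(inherits(fit, "sdem_fit"))
  if (!fit$include_lagged)
    stop("impacts need a fit with the spatially lagged covariate block",
         call. = FALSE)
  cf <- fit$coefficients
  dir <- cf[cf$block == "direct", ]
  lag <- cf[cf$block == "lag", ]
  stopifnot(identical(paste0("lag.", dir$name), lag$name))
  data.frame(
    name = dir$name,
    direct = dir$estimate, indirect = lag$estimate,
    total = dir$estimate + lag$estimate,
    direct_p = dir$p, indirect_p = lag$p,
    stringsAsFactors = FALSE
  )
}

#' Likelihood-ratio test between nested spatial fits
#'
#' Compares a full and a nested fit on the same data:
#' statistic \eqn{2(\ell_{full} - \ell_{nested})} (clamped at 0), degrees of
#' freedom the difference in parameter counts, p-value from the chi-square
#' upper tail. Used to compare the spatial Durbin error model against the
#' plain spatial error model (is the lag block needed?).
#'
#' @param fit_full,fit_nested \code{\link{fit_sdem}} objects; the nested
#'   model's columns must be a subset of the full model's.
#' @return List of class \code{"sdem_lrtest"}: \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
lr_test <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "sdem_fit"), inherits(fit_nested, "sdem_fit"))
  if (fit_full$n != fit_nested$n)
    stop("fits are not on the same data (different n)", call. = FALSE)
  if (!all(fit_nested$coefficients$name %in% fit_full$coefficients$name))
    stop("models are not nested: nested fit has columns absent from the full fit",
         call. = FALSE)
  df <- fit_full$npar - fit_nested$npar
  if (df < 0) stop("'fit_full' has fewer parameters than 'fit_nested'",
                   call. = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_nested$loglik))
  p <- if (df == 0) as.numeric(stat == 0) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  if (df == 0) p <- 1
  structure(list(statistic = stat, df = df, p_value = p),
            class = "sdem_lrtest")
}

#' @export
print.sdem_lrtest <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: LR = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
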