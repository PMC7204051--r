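#' Variance inflation factors and pairwise correlation screen
#'
#' Multicollinearity screen for a covariate table: each variable's VIF is
#' \eqn{1/(1 - R^2_k)} from regressing it on all other covariates (with
#' intercept), and every pair with absolute Pearson correlation above
#' \code{cor_threshold} is listed. The screen is advisory: it flags, it never
#' drops — which variable of a correlated pair to exclude is an analyst
#' decision recorded in the study configuration.
#'
#' @param X Numeric matrix or data frame of covariates (n > p + 1 rows, no
#'   constant columns).
#' @param threshold VIF flag threshold (default 10).
#' @param cor_threshold Pairwise |r| threshold (default 0.7).
#' @return List of class \code{"vif_report"}: \code{table} (variable, vif,
#'   flagged), \code{correlation_pairs} (var1, var2, r), and the thresholds.
#' @export
vif <- function(X, threshold = 10, cor_threshold = 0.7) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (nrow(X) <= p + 1)
    stop("need more observations than covariates plus intercept",
         call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)

  vifs <- vapply(seq_len(p), function(k) {
    if (p == 1) return(1)
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))

  cm <- stats::cor(X)
  idx <- which(upper.tri(cm) & abs(cm) > cor_threshold, arr.ind = TRUE)
  pairs <- data.frame(
    var1 = colnames(X)[idx[, 1]], var2 = colnames(X)[idx[, 2]],
    r = cm[idx], stringsAsFactors = FALSE
  )
  structure(list(
    table = data.frame(variable = colnames(X), vif = vifs,
                       flagged = vifs > threshold, stringsAsFactors = FALSE),
    correlation_pairs = pairs,
    threshold = threshold, cor_threshold = cor_threshold
  ), class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screen (flag > ", x$threshold, "):\n", sep = "")
  print(x$table, digits = 4)
  if (nrow(x$correlation_pairs)) {
    cat("Pairs with |r| > ", x$cor_threshold, ":\n", sep = "")
    print(x$correlation_pairs, digits = 3)
  }
  invisible(x)
}

#' Global Moran's I
#'
#' Moran's I of a tract-level variable under a spatial weights matrix,
#' \deqn{I = \frac{n}{S_0}\,\frac{e' W e}{e' e}, \qquad e = x - \bar x,
#'   \quad S_0 = \sum_{ij} w_{ij},}
#' with expectation \eqn{-1/(n-1)} under the null of no spatial
#' autocorrelation. Inference is by random permutation of the values
#' (default, two-sided on |I|: \eqn{p = (\#\{|I_{perm}| \ge |I_{obs}|\} + 1) /
#' (B + 1)}) or by the normal approximation with randomization moments.
#'
#' @param x Numeric values aligned to \code{w$ids}; must not be constant.
#' @param w Row-standardized \code{\link{spatial_weights}}.
#' @param n_permutations Number of permutations (default 999; ignored for
#'   the normal method).
#' @param seed Optional integer seed making the permutation p-value
#'   reproducible.
#' @param method \code{"permutation"} (default) or
#'   \code{"normal-approximation"}.
#' @return List of class \code{"moran_result"}: \code{I}, \code{expected_I},
#'   \code{p_value}, \code{method}, \code{n_permutations} (and \code{sd},
#'   \code{z} for the normal method).
#' @export
morans_i <- function(x, w, n_permutations = 999, seed = NULL,
                     method = c("permutation", "normal-approximation")) {
  method <- match.arg(method)
  stopifnot(inherits(w, "spatial_weights"))
  x <- as.numeric(x)
  n <- length(w$ids)
  if (length(x) != n) stop("'x' must have one value per tract", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("'x' has zero variance; Moran's I undefined", call. = FALSE)

  W <- w$W
  S0 <- sum(W)
  e <- x - mean(x)
  denom <- sum(e^2)
  I_obs <- (n / S0) * sum(e * as.numeric(W %*% e)) / denom
  expected <- -1 / (n - 1)

  if (method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    E <- vapply(seq_len(n_permutations), function(b) sample(e),
                numeric(n))
    I_perm <- (n / S0) * colSums(E * as.matrix(W %*% E)) / denom
    p <- (sum(abs(I_perm) >= abs(I_obs)) + 1) / (n_permutations + 1)
    structure(list(I = I_obs, expected_I = expected, p_value = p,
                   method = "permutation",
                   n_permutations = n_permutations),
              class = "moran_result")
  } else {
    Wd <- as.matrix(W)
    S1 <- sum((Wd + t(Wd))^2) / 2
    S2 <- sum((rowSums(Wd) + colSums(Wd))^2)
    b2 <- n * sum(e^4) / denom^2
    EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
           ((n - 1) * (n - 2) * (n - 3) * S0^2)
    v <- EI2 - expected^2
    z <- (I_obs - expected) / sqrt(v)
    structure(list(I = I_obs, expected_I = expected,
                   p_value = 2 * stats::pnorm(-abs(z)),
                   sd = sqrt(v), z = z,
                   method = "normal-approximation",
                   n_permutations = 0L),
              class = "moran_result")
  }
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), p = %.4g [%s]\n",
              x$I, x$expected_I, x$p_value, x$method))
  invisible(x)
}

#' Residual diagnostics: normality and heteroscedasticity
#'
#' Advisory checks on a fitted model's residuals. Normality uses the
#' moment-based Jarque-Bera statistic
#' \eqn{n(S^2/6 + K^2/24)} (S skewness, K excess kurtosis) against
#' \eqn{\chi^2_2}; heteroscedasticity regresses squared residuals on the
#' fitted values and tests the slope. Neither check blocks a pipeline run.
#'
#' @param residuals Model residuals (finite).
#' @param fitted Fitted values, same length.
#' @return List of class \code{"residual_checks"}: \code{normality}
#'   (statistic, p), \code{heteroscedasticity} (slope, p), and
#'   \code{degenerate} (TRUE when residuals are constant, tests skipped).
#' @export
residual_checks <- function(residuals, fitted) {
  residuals <- as.numeric(residuals)
  fitted <- as.numeric(fitted)
  stopifnot(length(residuals) == length(fitted),
            all(is.finite(residuals)), all(is.finite(fitted)))
  n <- length(residuals)
  if (stats::sd(residuals) == 0)
    return(structure(list(degenerate = TRUE, normality = NULL,
                          heteroscedasticity = NULL),
                     class = "residual_checks"))
  e <- residuals - mean(residuals)
  s2 <- mean(e^2)
  skew <- mean(e^3) / s2^1.5
  exk <- mean(e^4) / s2^2 - 3
  jb <- n * (skew^2 / 6 + exk^2 / 24)
  p_norm <- stats::pchisq(jb, df = 2, lower.tail = FALSE)

  het_fit <- stats::lm(I(residuals^2) ~ fitted)
  sm <- summary(het_fit)$coefficients
  het <- list(slope = sm[2, 1], p = sm[2, 4])

  structure(list(
    degenerate = FALSE,
    normality = list(statistic = jb, skewness = skew,
                     excess_kurtosis = exk, p = p_norm),
    heteroscedasticity = het
  ), class = "residual_checks")
}

#' @export
print.residual_checks <- function(x, ...) {
  if (x$degenerate) {
    cat("Residuals are constant; diagnostics skipped\n")
    return(invisible(x))
  }
  cat(sprintf("Normality (Jarque-Bera): stat = %.3f, p = %.4g\n",
              x$normality$statistic, x$normality$p))
  cat(sprintf("Heteroscedasticity (squared-residual slope): p = %.4g\n",
              x$heteroscedasticity$p))
  invisible(x)
}
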