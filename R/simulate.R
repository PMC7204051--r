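#' Spatially autocorrelated covariates on a lattice
#'
#' Draws covariate columns with first-order spatial autocorrelation:
#' \eqn{x_j = (I - \rho_x W)^{-1} \eta_j} with iid standard normal
#' \eqn{\eta_j}, then standardizes each column to mean 0, variance 1.
#' \eqn{\rho_x = 0} gives iid columns.
#'
#' @param w Row-standardized \code{\link{spatial_weights}}.
#' @param p Number of covariates.
#' @param rho Covariate spatial autocorrelation in the admissible interval
#'   of W.
#' @param seed Optional integer seed.
#' @return n x p numeric matrix, columns \code{x1..xp}, rows named by
#'   \code{w$ids}.
#' @export
simulate_covariates <- function(w, p = 2, rho = 0.6, seed = NULL) {
  stopifnot(inherits(w, "spatial_weights"), p >= 1)
  n <- length(w$ids)
  ev <- weights_eigenvalues(w)
  if (any(1 - rho * ev <= 0))
    stop("'rho' = ", rho, " outside the admissible interval of W",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- Matrix::Diagonal(n) - rho * w$W
  X <- vapply(seq_len(p), function(j) {
    x <- as.numeric(Matrix::solve(A, stats::rnorm(n)))
    as.numeric(scale(x))
  }, numeric(n))
  colnames(X) <- paste0("x", seq_len(p))
  rownames(X) <- w$ids
  X
}

#' Simulate an outcome from the spatial Durbin error model
#'
#' Data-generating twin of \code{\link{fit_sdem}}:
#' \deqn{y = \alpha + X\beta + WX\theta + u, \qquad
#'   u = (I - \lambda W)^{-1}\varepsilon, \quad
#'   \varepsilon \sim N(0, \sigma^2).}
#'
#' @param X Covariate matrix aligned to \code{w$ids}.
#' @param w Row-standardized \code{\link{spatial_weights}}.
#' @param alpha Intercept (years; default 80.75, a typical tract-level life
#'   expectancy level).
#' @param beta Direct effects, length \code{ncol(X)}.
#' @param theta Lag effects (NULL for none).
#' @param lambda Error spatial autocorrelation, admissible for W.
#' @param sigma Innovation standard deviation (years).
#' @param seed Optional integer seed.
#' @return Numeric outcome vector named by \code{w$ids}.
#' @export
simulate_sdem_outcome <- function(X, w, alpha = 80.75, beta, theta = NULL,
                                  lambda = 0.5, sigma = 1, seed = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  X <- as.matrix(X)
  n <- length(w$ids)
  stopifnot(nrow(X) == n, length(beta) == ncol(X),
            is.null(theta) || length(theta) == ncol(X), sigma >= 0)
  ev <- weights_eigenvalues(w)
  if (any(1 - lambda * ev <= 0))
    stop("'lambda' = ", lambda, " outside the admissible interval of W",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(n, 0, sigma)
  u <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - lambda * w$W, eps))
  y <- alpha + as.numeric(X %*% beta) + u
  if (!is.null(theta)) y <- y + as.numeric(spatial_lag(w, X) %*% theta)
  stats::setNames(y, w$ids)
}

#' Fixed synthetic age pyramid
#'
#' Population shares per age interval of the default 19-interval schedule:
#' a plausible declining pyramid (small infant share, broad working-age
#' plateau, tapering after 65). A fixture constant for simulation, not an
#' empirical claim about any real population.
#'
#' @return Numeric vector of 19 shares summing to 1.
#' @export
age_pyramid <- function() {
  shares <- c(0.011, 0.044, 0.055, 0.055, 0.060, 0.062, 0.062, 0.060,
              0.060, 0.062, 0.065, 0.068, 0.065, 0.060, 0.050, 0.042,
              0.034, 0.025, 0.020)
  shares / sum(shares)
}

#' Simulate age-structured mortality counts
#'
#' Gompertz-baseline Poisson mortality: in tract \eqn{i} and interval with
#' midpoint age \eqn{a}, the death rate is
#' \eqn{m_{ia} = a_0 e^{b a} e^{x_i'\delta}} per person-year; person-years
#' come from the fixed \code{\link{age_pyramid}} times the base population
#' and study length; deaths are Poisson draws \eqn{D \sim Pois(m \cdot PY)}
#' (or the expectations themselves with \code{expected = TRUE}, for
#' noise-free checks). The open interval's midpoint is taken at age 90.
#'
#' @param X Covariate matrix (one row per tract; row names used as ids when
#'   present).
#' @param schedule An \code{\link{age_schedule}}.
#' @param base_population Persons per tract spread over the pyramid
#'   (default 5000).
#' @param study_years Study window in years (default 5).
#' @param gompertz_a Baseline hazard at age 0 per person-year (default 5e-5).
#' @param gompertz_b Log-hazard slope per year of age (default 0.085).
#' @param delta Per-covariate multipliers on log-mortality (default all 0).
#' @param seed Optional integer seed.
#' @param expected Return expected (real-valued) deaths instead of Poisson
#'   draws.
#' @param ids Tract identifiers (default row names of X).
#' @return List: \code{mortality} (data frame \code{tract_id, d_00..}),
#'   \code{population} (data frame \code{tract_id, p_00..}).
#' @export
simulate_mortality <- function(X, schedule = age_schedule(),
                               base_population = 5000, study_years = 5,
                               gompertz_a = 5e-5, gompertz_b = 0.085,
                               delta = NULL, seed = NULL, expected = FALSE,
                               ids = rownames(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(ids)) ids <- sprintf("t%05d", seq_len(n))
  if (is.null(delta)) delta <- rep(0, ncol(X))
  stopifnot(length(delta) == ncol(X), gompertz_a > 0, gompertz_b > 0,
            base_population >= 0)
  n_int <- nrow(schedule)
  if (n_int != 19)
    stop("mortality simulation uses the default 19-interval schedule",
         call. = FALSE)
  mid <- ifelse(is.finite(schedule$width),
                schedule$start + schedule$width / 2, 90)
  base_rate <- gompertz_a * exp(gompertz_b * mid)
  pop <- round(age_pyramid() * base_population)
  py <- person_years_from_population(pop, study_years)
  rel <- exp(as.numeric(X %*% delta))

  if (!is.null(seed)) set.seed(seed)
  deaths <- t(vapply(seq_len(n), function(i) {
    mu <- base_rate * rel[i] * py
    if (expected) mu else stats::rpois(n_int, mu)
  }, numeric(n_int)))

  icol <- sprintf("%02d", seq_len(n_int) - 1)
  mort <- data.frame(tract_id = ids, deaths, stringsAsFactors = FALSE)
  names(mort) <- c("tract_id", paste0("d_", icol))
  popdf <- data.frame(tract_id = ids,
                      matrix(rep(pop, each = n), nrow = n),
                      stringsAsFactors = FALSE)
  names(popdf) <- c("tract_id", paste0("p_", icol))
  list(mortality = mort, population = popdf)
}

#' Write a lattice of unit-square tracts as GeoJSON
#'
#' @param rows,cols Grid dimensions.
#' @param path Output path.
#' @param ids Cell ids in row-major order (defaults match
#'   \code{\link{grid_queen_contiguity}}).
#' @return \code{path}, invisibly.
#' @export
write_grid_geojson <- function(rows, cols, path, ids = NULL) {
  n <- rows * cols
  if (is.null(ids)) ids <- sprintf("t%05d", seq_len(n))
  features <- vector("list", n)
  k <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    x0 <- c - 1; y0 <- r - 1
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    features[[k]] <- list(
      type = "Feature",
      properties = list(id = ids[k]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
    k <- k + 1L
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.fixture_registry <- list(
  tiny       = list(rows = 5,  cols = 5,  seed = 101L),
  recovery   = list(rows = 30, cols = 30, seed = 202L),
  filterable = list(rows = 6,  cols = 6,  seed = 303L)
)

# integer death counts with an exact total (largest-remainder rounding)
.round_to_total <- function(x, total) {
  if (sum(x) <= 0) return(c(total, rep(0, length(x) - 1)))
  scaled <- x / sum(x) * total
  fl <- floor(scaled)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(scaled - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Write a bundled synthetic study fixture
#'
#' Generates a complete synthetic study on disk: mortality and population
#' CSVs, a covariate CSV, a direct-mode outcome CSV, the lattice GeoJSON, a
#' GAL neighbor file, and a \code{truth.json} recording every true parameter
#' and seed. Each fixture name maps to a fixed configuration and seed, so
#' regenerating a fixture is byte-identical.
#'
#' Registered fixtures:
#' \describe{
#'   \item{tiny}{5 x 5 lattice; quick end-to-end runs.}
#'   \item{recovery}{30 x 30 lattice with lambda = 0.5, beta = (1, -0.5),
#'     theta = (0.3, 0), sigma = 1; parameter-recovery studies.}
#'   \item{filterable}{6 x 6 lattice containing tracts engineered to fail
#'     each reliability criterion (49 total deaths; 4995 person-years; a
#'     small-exposure tract with SE > 2 years) plus one boundary tract with
#'     exactly 50 deaths that passes every screen.}
#' }
#'
#' @param name One of \code{"tiny"}, \code{"recovery"}, \code{"filterable"}.
#' @param dir Output directory (created if needed).
#' @return Invisible list of the written file paths and the truth record.
#' @export
make_fixture <- function(name, dir) {
  cfg <- .fixture_registry[[name]]
  if (is.null(cfg))
    stop("unknown fixture '", name, "'; registered: ",
         paste(names(.fixture_registry), collapse = ", "), call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  adj <- grid_queen_contiguity(cfg$rows, cfg$cols)
  w <- row_standardize(adj)
  truth <- list(
    name = name, rows = cfg$rows, cols = cfg$cols, seed = cfg$seed,
    rho_x = 0.6, p = 2,
    alpha = 80.75, beta = c(1.0, -0.5), theta = c(0.3, 0.0),
    lambda = 0.5, sigma = 1,
    gompertz_a = 5e-5, gompertz_b = 0.085, delta = c(-0.1, 0.05),
    base_population = 5000, study_years = 5
  )

  X <- simulate_covariates(w, p = truth$p, rho = truth$rho_x,
                           seed = cfg$seed)
  y <- simulate_sdem_outcome(X, w, alpha = truth$alpha, beta = truth$beta,
                             theta = truth$theta, lambda = truth$lambda,
                             sigma = truth$sigma, seed = cfg$seed + 1L)
  sim <- simulate_mortality(X, base_population = truth$base_population,
                            study_years = truth$study_years,
                            gompertz_a = truth$gompertz_a,
                            gompertz_b = truth$gompertz_b,
                            delta = truth$delta, seed = cfg$seed + 2L)

  if (name == "filterable") {
    sched <- age_schedule()
    ids <- w$ids
    eng <- list()
    exp_sim <- simulate_mortality(X, base_population = truth$base_population,
                                  study_years = truth$study_years,
                                  gompertz_a = truth$gompertz_a,
                                  gompertz_b = truth$gompertz_b,
                                  delta = truth$delta, expected = TRUE)
    shape <- as.numeric(exp_sim$mortality[1, -1])

    # (a) 49 total deaths, ample person-years -> fails the deaths screen
    i <- match(ids[2], sim$mortality$tract_id)
    sim$mortality[i, -1] <- as.list(.round_to_total(shape, 49))
    sim$population[i, -1] <- as.list(round(age_pyramid() * 20000))
    eng$deaths49 <- ids[2]

    # (b) 999 persons -> 4995 person-years -> fails the person-years screen
    i <- match(ids[9], sim$mortality$tract_id)
    pop_b <- .round_to_total(age_pyramid() * 999, 999)
    sim$population[i, -1] <- as.list(pop_b)
    mu_b <- truth$gompertz_a *
      exp(truth$gompertz_b * ifelse(is.finite(sched$width),
                                    sched$start + sched$width / 2, 90)) *
      person_years_from_population(pop_b, truth$study_years)
    sim$mortality[i, -1] <- as.list(.round_to_total(mu_b, 60))
    eng$py4995 <- ids[9]

    # (c) modest deaths over small exposures -> SE above 2 years
    i <- match(ids[16], sim$mortality$tract_id)
    pop_c <- .round_to_total(age_pyramid() * 1400, 1400)
    sim$population[i, -1] <- as.list(pop_c)
    mu_c <- truth$gompertz_a *
      exp(truth$gompertz_b * ifelse(is.finite(sched$width),
                                    sched$start + sched$width / 2, 90)) *
      person_years_from_population(pop_c, truth$study_years)
    sim$mortality[i, -1] <- as.list(.round_to_total(mu_c, 55))
    eng$se_high <- ids[16]

    # boundary tract: exactly 50 deaths, all in the open interval, with
    # enough exposure there that the SE stays low -> passes every screen
    i <- match(ids[23], sim$mortality$tract_id)
    d_bound <- rep(0, nrow(sched)); d_bound[nrow(sched)] <- 50
    pop_d <- round(age_pyramid() * 20000); pop_d[nrow(sched)] <- 100
    sim$mortality[i, -1] <- as.list(d_bound)
    sim$population[i, -1] <- as.list(pop_d)
    eng$boundary50 <- ids[23]

    truth$engineered <- eng
    le <- tract_life_expectancy(sim$mortality, sim$population)
    truth$expected_verdicts <- stats::setNames(
      as.list(le$reasons), le$tract_id)[unlist(eng)]
  }

  paths <- list(
    mortality  = file.path(dir, "mortality.csv"),
    population = file.path(dir, "population.csv"),
    covariates = file.path(dir, "covariates.csv"),
    outcome    = file.path(dir, "outcome.csv"),
    geojson    = file.path(dir, "grid.geojson"),
    gal        = file.path(dir, "neighbors.gal"),
    truth      = file.path(dir, "truth.json")
  )
  utils::write.csv(sim$mortality, paths$mortality, row.names = FALSE)
  utils::write.csv(sim$population, paths$population, row.names = FALSE)
  utils::write.csv(data.frame(tract_id = w$ids, X, stringsAsFactors = FALSE),
                   paths$covariates, row.names = FALSE)
  utils::write.csv(data.frame(tract_id = w$ids, e0 = as.numeric(y),
                              stringsAsFactors = FALSE),
                   paths$outcome, row.names = FALSE)
  write_grid_geojson(cfg$rows, cfg$cols, paths$geojson)
  write_gal(adj, paths$gal)
  truth$package_version <- as.character(utils::packageVersion("tractlife"))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
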