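#' Abridged life table by the adjusted Chiang II method
#'
#' Builds an abridged life table from deaths and person-years per age
#' interval. Age-specific death rates are \eqn{m_i = D_i / PY_i}; the
#' probability of dying within a closed interval of width \eqn{n_i} is
#' \deqn{q_i = n_i m_i / (1 + n_i (1 - a_i) m_i),}
#' clamped to at most 1, with \eqn{q = 1} in the open-ended final interval.
#' Survivorship \eqn{l}, life-table deaths \eqn{d}, person-years lived
#' \eqn{L}, cumulative person-years \eqn{T} and remaining life expectancy
#' \eqn{e} follow the standard recursions, with the open interval
#' contributing \eqn{L = l / m} (exponential tail at the terminal rate).
#'
#' An empty closed stratum (zero deaths and zero person-years) is treated as
#' rate 0, so tracts with no deaths in an age group remain computable.
#' Deaths with no exposure are an error, as is a positive number of survivors
#' reaching an open interval whose rate is zero: no rate floor is
#' substituted, the caller must merge intervals or reject the tract.
#'
#' @param deaths Non-negative deaths per interval \eqn{D_i}.
#' @param person_years Non-negative person-years per interval \eqn{PY_i}.
#' @param schedule An \code{\link{age_schedule}}.
#' @param radix Survivors at age 0 (default 100000).
#' @return Data frame of class \code{"life_table"} with the schedule columns
#'   plus \code{deaths}, \code{person_years}, \code{m}, \code{q}, \code{l},
#'   \code{d}, \code{L}, \code{T}, \code{e}; the radix is stored as an
#'   attribute. \code{e[1]} is life expectancy at birth.
#' @examples
#' sched <- age_schedule()
#' D  <- c(rep(0, 18), 100)
#' PY <- c(rep(1000, 18), 100 / 0.02)
#' lt <- life_table(D, PY, sched)
#' lt$e[1]   # 85 + 1/0.02 = 135
#' @export
life_table <- function(deaths, person_years, schedule = age_schedule(),
                       radix = 1e5) {
  n_int <- nrow(schedule)
  if (length(deaths) != n_int || length(person_years) != n_int)
    stop("'deaths' and 'person_years' must have one value per schedule interval",
         call. = FALSE)
  if (any(!is.finite(deaths)) || any(deaths < 0))
    stop("'deaths' must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(person_years)) || any(person_years < 0))
    stop("'person_years' must be finite and non-negative", call. = FALSE)

  bad <- deaths > 0 & person_years == 0
  if (any(bad))
    stop("deaths with zero person-years (infinite rate) in interval(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)

  m <- ifelse(person_years > 0, deaths / person_years, 0)
  nw <- schedule$width
  a  <- schedule$a

  closed <- is.finite(nw)
  q <- numeric(n_int)
  q[closed] <- pmin(1, nw[closed] * m[closed] /
                       (1 + nw[closed] * (1 - a[closed]) * m[closed]))
  q[!closed] <- 1

  l <- radix * cumprod(c(1, 1 - q[-n_int]))
  d <- l * q

  L <- numeric(n_int)
  L[closed] <- nw[closed] * (l[closed] - (1 - a[closed]) * d[closed])
  open <- n_int
  if (l[open] > 0) {
    if (m[open] <= 0)
      stop("survivors reach the open interval but its death rate is zero; ",
           "cannot close the table (merge intervals or reject)", call. = FALSE)
    L[open] <- l[open] / m[open]
  } else {
    L[open] <- 0
  }

  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  out <- data.frame(
    start = schedule$start, width = nw, a = a,
    deaths = deaths, person_years = person_years,
    m = m, q = q, l = l, d = d, L = L, T = Tx, e = e
  )
  attr(out, "radix") <- radix
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life expectancy at birth with Chiang-style standard error
#'
#' Extracts \eqn{e_0} from a life table and attaches its sampling standard
#' error and a normal confidence interval. The variance of each closed
#' interval's death probability is the binomial-style
#' \eqn{Var(q_i) = q_i^2 (1 - q_i) / D_i} (zero when the interval has no
#' deaths); these propagate to
#' \deqn{Var(e_0) = \sum_i l_i^2 [(1 - a_i) n_i + e_{i+1}]^2 Var(q_i) / \ell_0^2}
#' over closed intervals, plus the final-interval adjustment
#' \eqn{(l_{open}/\ell_0)^2 / (m_{open}^2 D_{open})} accounting for sampling
#' error in the terminal rate.
#'
#' @param lt A \code{\link{life_table}} (carries its deaths column).
#' @param conf_level Confidence level for the normal interval (default 0.95).
#' @param tract_id Optional identifier carried into the result.
#' @return One-row data frame: \code{tract_id}, \code{e0}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{total_deaths},
#'   \code{total_person_years}.
#' @export
life_expectancy <- function(lt, conf_level = 0.95, tract_id = NA_character_) {
  stopifnot(inherits(lt, "life_table"))
  radix <- attr(lt, "radix")
  n_int <- nrow(lt)
  closed <- is.finite(lt$width)

  var_q <- ifelse(closed & lt$deaths > 0,
                  lt$q^2 * (1 - lt$q) / lt$deaths, 0)
  e_next <- c(lt$e[-1], 0)
  wgt <- (1 - lt$a) * lt$width + e_next
  contrib <- ifelse(closed, lt$l^2 * wgt^2 * var_q, 0) / radix^2
  v <- sum(contrib)

  open <- n_int
  if (lt$deaths[open] > 0 && lt$m[open] > 0)
    v <- v + (lt$l[open] / radix)^2 / (lt$m[open]^2 * lt$deaths[open])

  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  e0 <- lt$e[1]
  data.frame(
    tract_id = tract_id,
    e0 = e0, se = se,
    ci_low = e0 - zq * se, ci_high = e0 + zq * se,
    total_deaths = sum(lt$deaths),
    total_person_years = sum(lt$person_years),
    stringsAsFactors = FALSE
  )
}

#' Reliability criteria for small-area life expectancy estimates
#'
#' Threshold set used to screen tract-level estimates: a tract is excluded
#' when its total deaths fall below \code{min_deaths}, its total person-years
#' below \code{min_person_years}, or the standard error of \eqn{e_0} exceeds
#' \code{max_se} years. All comparisons are strict, so a tract sitting
#' exactly on a threshold (50 deaths, 5000 person-years, SE of 2.0) is
#' retained.
#'
#' @param min_deaths Minimum total deaths (default 50).
#' @param min_person_years Minimum total person-years (default 5000).
#' @param max_se Maximum standard error in years (default 2).
#' @return List of class \code{"reliability_criteria"}.
#' @export
reliability_criteria <- function(min_deaths = 50, min_person_years = 5000,
                                 max_se = 2) {
  if (min_deaths <= 0 || min_person_years <= 0 || max_se <= 0)
    stop("all reliability thresholds must be positive", call. = FALSE)
  structure(list(min_deaths = min_deaths,
                 min_person_years = min_person_years,
                 max_se = max_se),
            class = "reliability_criteria")
}

#' Screen life expectancy estimates for reliability
#'
#' Applies \code{\link{reliability_criteria}} to one or more estimates. A
#' tract fails when \code{total_deaths < min_deaths},
#' \code{total_person_years < min_person_years}, or \code{se > max_se}; all
#' failed criteria are reported (labels \code{"deaths"},
#' \code{"person_years"}, \code{"se"}).
#'
#' @param est Data frame with columns \code{total_deaths},
#'   \code{total_person_years}, \code{se} (as returned by
#'   \code{\link{life_expectancy}} or \code{\link{tract_life_expectancy}}).
#' @param criteria A \code{\link{reliability_criteria}} object.
#' @return \code{est} with added columns \code{retained} (logical) and
#'   \code{reasons} (semicolon-separated failed criteria, \code{""} when
#'   retained).
#' @export
assess_reliability <- function(est, criteria = reliability_criteria()) {
  stopifnot(inherits(criteria, "reliability_criteria"),
            all(c("total_deaths", "total_person_years", "se") %in% names(est)))
  fail_d  <- est$total_deaths < criteria$min_deaths
  fail_py <- est$total_person_years < criteria$min_person_years
  fail_se <- est$se > criteria$max_se
  reasons <- mapply(function(d, p, s) {
    paste(c(if (d) "deaths", if (p) "person_years", if (s) "se"),
          collapse = ";")
  }, fail_d, fail_py, fail_se)
  est$retained <- !(fail_d | fail_py | fail_se)
  est$reasons <- as.character(reasons)
  est
}

#' Tract-level life expectancy from mortality and population tables
#'
#' End-to-end estimation for a set of tracts: joins a deaths table and a
#' population table by tract identifier (inner join), converts population to
#' person-years, computes each tract's life table and \eqn{e_0} with its
#' standard error, and screens the estimates against the reliability
#' criteria.
#'
#' Input tables use one row per tract: a \code{tract_id} column followed by
#' one column per schedule interval, in schedule order (\code{d_00..d_18} for
#' deaths, \code{p_00..p_18} for population in the default 19-interval
#' schedule; any column names are accepted, order is what matters).
#'
#' @param mortality Data frame: \code{tract_id} plus deaths per interval.
#' @param population Data frame: \code{tract_id} plus population per interval.
#' @param schedule An \code{\link{age_schedule}}.
#' @param study_years Study period length in years (default 5).
#' @param radix Life-table radix (default 100000).
#' @param criteria \code{\link{reliability_criteria}} used for screening.
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return Data frame, one row per joined tract, sorted by tract id:
#'   \code{tract_id}, \code{e0}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{total_deaths}, \code{total_person_years}, \code{retained},
#'   \code{reasons}. Tracts whose life table cannot be closed (degenerate
#'   open interval) get \code{NA} estimates and are marked not retained with
#'   reason \code{"degenerate"}.
#' @export
tract_life_expectancy <- function(mortality, population,
                                  schedule = age_schedule(),
                                  study_years = 5, radix = 1e5,
                                  criteria = reliability_criteria(),
                                  conf_level = 0.95) {
  n_int <- nrow(schedule)
  if (ncol(mortality) != n_int + 1L || ncol(population) != n_int + 1L)
    stop("mortality and population tables need tract_id plus ", n_int,
         " interval columns", call. = FALSE)
  ids <- intersect(mortality[[1]], population[[1]])
  if (length(ids) == 0L)
    stop("no tract ids shared between mortality and population tables",
         call. = FALSE)
  ids <- sort(as.character(ids), method = "radix")
  mi <- match(ids, as.character(mortality[[1]]))
  pi <- match(ids, as.character(population[[1]]))

  rows <- lapply(seq_along(ids), function(i) {
    D  <- as.numeric(mortality[mi[i], -1])
    PY <- person_years_from_population(as.numeric(population[pi[i], -1]),
                                       study_years)
    est <- tryCatch({
      lt <- life_table(D, PY, schedule, radix)
      life_expectancy(lt, conf_level, tract_id = ids[i])
    }, error = function(e) {
      data.frame(tract_id = ids[i], e0 = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 total_deaths = sum(D), total_person_years = sum(PY),
                 stringsAsFactors = FALSE)
    })
    est
  })
  est <- do.call(rbind, rows)
  ok <- !is.na(est$e0)
  out <- est
  out$retained <- FALSE
  out$reasons <- "degenerate"
  if (any(ok)) {
    scr <- assess_reliability(est[ok, , drop = FALSE], criteria)
    out$retained[ok] <- scr$retained
    out$reasons[ok] <- scr$reasons
  }
  rownames(out) <- NULL
  out
}
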