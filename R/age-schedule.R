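#' Abridged age schedule
#'
#' Constructs the abridged age schedule used throughout the package: a set of
#' contiguous age intervals, each carrying its width in years and the average
#' fraction of the interval lived by those who die within it (Chiang's
#' \eqn{a_i}). The final interval is always open-ended.
#'
#' The default is the 19-interval schedule standard in small-area mortality
#' work: under 1 year, 1--4, sixteen five-year intervals, and 85+. The
#' default \code{a_fraction = 0.5} encodes the assumption that deaths are
#' spread evenly throughout each age interval; practice sometimes uses a
#' smaller fraction for the infant interval (e.g. 0.1), which can be supplied
#' per interval.
#'
#' @param breaks Increasing integer vector of interval start ages; the first
#'   must be 0. The last break opens the final, open-ended interval.
#' @param a_fraction Fraction of interval lived by decedents, in \[0, 1\];
#'   recycled to the number of intervals.
#' @return A data frame of class \code{"age_schedule"} with columns
#'   \code{start}, \code{width} (\code{Inf} for the open interval) and
#'   \code{a}.
#' @examples
#' sched <- age_schedule()
#' nrow(sched)            # 19
#' sched$start[19]        # 85
#' @export
age_schedule <- function(breaks = c(0, 1, seq(5, 85, by = 5)),
                         a_fraction = 0.5) {
  if (length(breaks) < 1L || breaks[1] != 0)
    stop("'breaks' must start at age 0", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("'breaks' must be strictly increasing", call. = FALSE)
  n <- length(breaks)
  a <- rep_len(a_fraction, n)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("'a_fraction' must lie in [0, 1]", call. = FALSE)
  out <- data.frame(
    start = breaks,
    width = c(diff(breaks), Inf),
    a     = a
  )
  class(out) <- c("age_schedule", "data.frame")
  out
}

#' Person-years of exposure from population counts
#'
#' Converts age-specific population counts into person-years of exposure by
#' multiplying by the length of the study period, the convention used when a
#' single census count serves as the denominator for several years of deaths
#' (e.g. a five-year mortality window over a decennial count).
#'
#' @param population Non-negative population count per age interval.
#' @param study_years Length of the study period in years (integer >= 1).
#' @return Numeric vector of person-years, same length as \code{population}.
#' @examples
#' person_years_from_population(rep(1000, 19), study_years = 5)
#' @export
person_years_from_population <- function(population, study_years = 5) {
  if (!is.numeric(population) || any(!is.finite(population)))
    stop("'population' must be finite numeric", call. = FALSE)
  if (any(population < 0))
    stop("'population' must be non-negative", call. = FALSE)
  if (!is.numeric(study_years) || length(study_years) != 1L ||
      !is.finite(study_years) || study_years < 1)
    stop("'study_years' must be a single number >= 1", call. = FALSE)
  population * study_years
}
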