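#' Study configuration
#'
#' Collects every knob of an end-to-end run: input paths, the reliability
#' screen, covariate exclusions, model and diagnostics options. The outcome
#' is either computed from the mortality/population tables
#' (\code{outcome_mode = "lifetable"}, the default) or read from a CSV of
#' precomputed values (\code{outcome_mode = "file"}), which the synthetic
#' fixtures use for sharp parameter-recovery runs.
#'
#' @param mortality,population Paths to the deaths and population CSVs
#'   (tract_id plus one column per age interval).
#' @param covariates Path to the covariate CSV (tract_id plus covariate
#'   columns).
#' @param geojson,gal Tract geometry (GeoJSON) or precomputed neighbor file
#'   (GAL); exactly one must be given.
#' @param outcome Path to an outcome CSV (tract_id, e0) for
#'   \code{outcome_mode = "file"}.
#' @param outcome_mode \code{"lifetable"} or \code{"file"}.
#' @param study_years Study window for person-years (default 5).
#' @param apply_filters Apply the reliability screen (default TRUE;
#'   \code{FALSE} reproduces a sensitivity run over all tracts).
#' @param criteria A \code{\link{reliability_criteria}}.
#' @param excluded_covariates Covariate columns dropped before modelling
#'   (the analyst's multicollinearity decision).
#' @param include_lagged Include the WX block in the model (default TRUE).
#' @param drop_islands Drop zero-neighbor tracts before fitting
#'   (default TRUE).
#' @param permutations Moran permutations for the residual test
#'   (default 999).
#' @param seed Seed for the permutation test (default 1).
#' @param conf_level Confidence level for life-expectancy intervals.
#' @return List of class \code{"study_config"}.
#' @export
study_config <- function(mortality = NULL, population = NULL,
                         covariates = NULL, geojson = NULL, gal = NULL,
                         outcome = NULL,
                         outcome_mode = c("lifetable", "file"),
                         study_years = 5, apply_filters = TRUE,
                         criteria = reliability_criteria(),
                         excluded_covariates = character(0),
                         include_lagged = TRUE, drop_islands = TRUE,
                         permutations = 999, seed = 1,
                         conf_level = 0.95) {
  outcome_mode <- match.arg(outcome_mode)
  if (is.null(geojson) == is.null(gal))
    stop("give exactly one of 'geojson' or 'gal'", call. = FALSE)
  if (outcome_mode == "file" && is.null(outcome))
    stop("outcome_mode = 'file' needs an 'outcome' path", call. = FALSE)
  if (outcome_mode == "lifetable" &&
      (is.null(mortality) || is.null(population)))
    stop("outcome_mode = 'lifetable' needs 'mortality' and 'population' paths",
         call. = FALSE)
  if (is.null(covariates)) stop("'covariates' path is required", call. = FALSE)
  structure(list(
    mortality = mortality, population = population, covariates = covariates,
    geojson = geojson, gal = gal, outcome = outcome,
    outcome_mode = outcome_mode, study_years = study_years,
    apply_filters = apply_filters, criteria = criteria,
    excluded_covariates = as.character(excluded_covariates),
    include_lagged = include_lagged, drop_islands = drop_islands,
    permutations = permutations, seed = seed, conf_level = conf_level
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' YAML keys mirror the arguments of \code{\link{study_config}};
#' \code{criteria} may be a mapping with \code{min_deaths},
#' \code{min_person_years}, \code{max_se}. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A \code{\link{study_config}}.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("mortality", "population", "covariates", "geojson", "gal",
                "outcome"))
    if (!is.null(raw[[key]]) && !grepl("^(/|[A-Za-z]:)", raw[[key]]))
      raw[[key]] <- file.path(base, raw[[key]])
  if (!is.null(raw$criteria))
    raw$criteria <- do.call(reliability_criteria, raw$criteria)
  do.call(study_config, raw)
}

#' Run a complete small-area life expectancy study
#'
#' Orchestrates the full analysis: load the inputs, estimate tract life
#' expectancy (or read a precomputed outcome), screen for reliability,
#' restrict the spatial weights to the retained tracts and re-standardize,
#' screen covariates for multicollinearity (advisory), fit the spatial
#' Durbin error model, decompose impacts, and test the model residuals for
#' remaining spatial autocorrelation with global Moran's I. Tables are
#' joined by tract id (inner join); orphan counts are recorded.
#'
#' @param config A \code{\link{study_config}}.
#' @return List of class \code{"study_report"}: \code{le} (estimates with
#'   verdicts), \code{counts} (total/retained/removed, removed per reason,
#'   join orphans, islands dropped), \code{fit} (the \code{sdem_fit}),
#'   \code{coefficients} (table with stars), \code{impacts}, \code{vif},
#'   \code{moran} (residual Moran's I), \code{residual_checks},
#'   \code{provenance}.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))

  adj <- if (!is.null(config$gal)) read_gal(config$gal)
         else queen_contiguity(config$geojson)
  cov_tab <- utils::read.csv(config$covariates, stringsAsFactors = FALSE)
  cov_tab[[1]] <- as.character(cov_tab[[1]])

  if (config$outcome_mode == "lifetable") {
    mort <- utils::read.csv(config$mortality, stringsAsFactors = FALSE)
    pop <- utils::read.csv(config$population, stringsAsFactors = FALSE)
    le <- tract_life_expectancy(mort, pop, study_years = config$study_years,
                                criteria = config$criteria,
                                conf_level = config$conf_level)
  } else {
    out_tab <- utils::read.csv(config$outcome, stringsAsFactors = FALSE)
    le <- data.frame(tract_id = as.character(out_tab[[1]]),
                     e0 = as.numeric(out_tab[[2]]),
                     se = 0, ci_low = NA_real_, ci_high = NA_real_,
                     total_deaths = NA_real_, total_person_years = NA_real_,
                     retained = TRUE, reasons = "",
                     stringsAsFactors = FALSE)
    le <- le[order(le$tract_id, method = "radix"), ]
  }

  total <- nrow(le)
  removed <- le[!le$retained, , drop = FALSE]
  analysis_le <- if (config$apply_filters)
    le[le$retained, , drop = FALSE] else le[!is.na(le$e0), , drop = FALSE]

  ids <- intersect(intersect(analysis_le$tract_id, cov_tab[[1]]), adj$ids)
  orphans <- list(
    le_only = setdiff(analysis_le$tract_id, ids),
    covariates_only = setdiff(cov_tab[[1]],
                              union(ids, le$tract_id[!le$retained]))
  )
  if (length(ids) == 0L)
    stop("empty join between life expectancy, covariates and geometry; ",
         "LE ids e.g. ", paste(utils::head(analysis_le$tract_id, 3),
                               collapse = ", "),
         "; covariate ids e.g. ", paste(utils::head(cov_tab[[1]], 3),
                                        collapse = ", "), call. = FALSE)
  ids <- sort(ids, method = "radix")

  sub_adj <- subset_adjacency(adj, ids)
  islands_dropped <- character(0)
  if (config$drop_islands) {
    deg <- lengths(sub_adj$neighbors)
    if (any(deg == 0)) {
      islands_dropped <- sub_adj$ids[deg == 0]
      warning("dropping ", length(islands_dropped),
              " island tract(s) before estimation", call. = FALSE)
      ids <- setdiff(ids, islands_dropped)
      sub_adj <- subset_adjacency(adj, ids)
    }
  }
  w <- suppressWarnings(row_standardize(sub_adj))

  y <- analysis_le$e0[match(ids, analysis_le$tract_id)]
  Xfull <- cov_tab[match(ids, cov_tab[[1]]), -1, drop = FALSE]
  keep_cols <- setdiff(names(Xfull), config$excluded_covariates)
  X <- as.matrix(Xfull[, keep_cols, drop = FALSE])

  vif_rep <- vif(X)
  fit <- fit_sdem(y, X, w, include_lagged = config$include_lagged)
  imp <- if (config$include_lagged) impacts(fit) else NULL
  moran <- morans_i(fit$residuals, w,
                    n_permutations = config$permutations,
                    seed = config$seed)
  checks <- residual_checks(fit$residuals, fit$fitted_trend)

  coefs <- fit$coefficients
  coefs$stars <- significance_stars(coefs$p)

  reason_counts <- table(unlist(strsplit(removed$reasons, ";")))
  structure(list(
    le = le,
    counts = list(total = total, retained = sum(le$retained),
                  removed = total - sum(le$retained),
                  removed_by_reason = as.list(reason_counts),
                  orphans = lapply(orphans, length),
                  islands_dropped = length(islands_dropped),
                  analyzed = length(ids)),
    fit = fit, coefficients = coefs, impacts = imp,
    vif = vif_rep, moran = moran, residual_checks = checks,
    analysis_ids = ids,
    provenance = list(
      package_version = as.character(utils::packageVersion("tractlife")),
      seed = config$seed,
      config = unclass(config)[!vapply(unclass(config), is.null,
                                       logical(1))]
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Small-area life expectancy study\n")
  cat(sprintf("Tracts: %d total, %d retained, %d removed; %d analyzed\n",
              x$counts$total, x$counts$retained, x$counts$removed,
              x$counts$analyzed))
  print(x$fit)
  print(x$moran)
  invisible(x)
}

.render_estimate <- function(est, stars) {
  paste0(format(est, trim = TRUE, digits = 3), stars)
}

#' Write study outputs to disk
#'
#' Emits the study's tables: \code{le.csv} (estimates with verdicts),
#' \code{coefficients.csv} (one row per covariate with the direct and
#' spatially lagged estimate, each with its significance stars, plus a
#' rendered \code{"0.13***"}-style label), \code{diagnostics.json} (VIF,
#' Moran, residual checks, model summary, counts, provenance) and
#' \code{run_log.txt}. Output is deterministic given identical inputs.
#'
#' @param report A \code{\link{run_study}} result.
#' @param outdir Output directory (created if needed).
#' @return Invisible character vector of the written paths.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p_le <- file.path(outdir, "le.csv")
  utils::write.csv(report$le, p_le, row.names = FALSE)

  cf <- report$coefficients
  dir_cf <- cf[cf$block == "direct", ]
  lag_cf <- cf[cf$block == "lag", ]
  tab <- data.frame(
    indicator = dir_cf$name,
    direct = dir_cf$estimate,
    direct_stars = dir_cf$stars,
    direct_label = .render_estimate(dir_cf$estimate, dir_cf$stars),
    stringsAsFactors = FALSE
  )
  if (nrow(lag_cf)) {
    m <- match(paste0("lag.", tab$indicator), lag_cf$name)
    tab$lag <- lag_cf$estimate[m]
    tab$lag_stars <- lag_cf$stars[m]
    tab$lag_label <- .render_estimate(lag_cf$estimate[m], lag_cf$stars[m])
  }
  p_cf <- file.path(outdir, "coefficients.csv")
  utils::write.csv(tab, p_cf, row.names = FALSE)

  diag <- list(
    model = list(
      lambda = report$fit$lambda, lambda_se = report$fit$lambda_se,
      sigma2 = report$fit$sigma2, loglik = report$fit$loglik,
      aic = report$fit$aic, n = report$fit$n, k = report$fit$k,
      r_squared = report$fit$r_squared,
      r_squared_definition = "squared Pearson correlation of observed outcome and trend prediction Z*gamma"
    ),
    coefficients = report$coefficients,
    impacts = report$impacts,
    vif = list(table = report$vif$table,
               correlation_pairs = report$vif$correlation_pairs,
               threshold = report$vif$threshold,
               cor_threshold = report$vif$cor_threshold),
    moran = unclass(report$moran),
    residual_checks = unclass(report$residual_checks),
    counts = report$counts,
    provenance = report$provenance
  )
  p_json <- file.path(outdir, "diagnostics.json")
  jsonlite::write_json(diag, p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

  p_log <- file.path(outdir, "run_log.txt")
  lines <- c(
    paste("tractlife", report$provenance$package_version),
    sprintf("tracts total=%d retained=%d removed=%d analyzed=%d",
            report$counts$total, report$counts$retained,
            report$counts$removed, report$counts$analyzed),
    sprintf("islands dropped: %d", report$counts$islands_dropped),
    sprintf("lambda=%.6f loglik=%.6f aic=%.6f r2=%.6f",
            report$fit$lambda, report$fit$loglik, report$fit$aic,
            report$fit$r_squared),
    sprintf("residual Moran I=%.6f p=%.6g (%s, %d permutations, seed %s)",
            report$moran$I, report$moran$p_value, report$moran$method,
            report$moran$n_permutations,
            format(report$provenance$seed))
  )
  writeLines(lines, p_log)
  invisible(c(p_le, p_cf, p_json, p_log))
}
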