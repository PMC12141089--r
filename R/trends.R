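#' Fit an effort-corrected linear trend of position on year
#'
#' Ordinary least squares of an annual positional metric (a centroid
#' coordinate or range limit, in degrees) on year, with the matching
#' metric computed over all checklists — the observer-effort covariate —
#' absorbing shifts in where people go birding. The reported slope,
#' standard error and two-sided t-test p-value are for the year
#' coefficient; the adjusted R-squared is for the full model. The
#' variance inflation factor between year and the covariate,
#' `1 / (1 - r^2(year, covariate))`, is reported as the collinearity
#' diagnostic.
#'
#' Region-years with any missing value are dropped pairwise. With fewer
#' than four complete (year, response, covariate) triples the fit is not
#' attempted and the result carries status `"INSUFFICIENT"`.
#'
#' @param years integer vector.
#' @param response numeric vector of positions, degrees.
#' @param covariate numeric effort covariate, degrees; `NULL` fits the
#'   uncorrected model `response ~ year`.
#' @return a list: `slope`, `se`, `p`, `adj_r2`, `vif` (`NA` when no
#'   covariate), `n_years`, `status` (`"OK"` or `"INSUFFICIENT"`).
#' @export
fitTrend <- function(years, response, covariate = NULL) {
  stopifnot(length(years) == length(response))
  insufficient <- list(slope = NA_real_, se = NA_real_, p = NA_real_,
                       adj_r2 = NA_real_, vif = NA_real_,
                       n_years = 0L, status = "INSUFFICIENT")
  if (is.null(covariate)) {
    ok <- is.finite(years) & is.finite(response)
    if (sum(ok) < 4L) { insufficient$n_years <- sum(ok); return(insufficient) }
    fit <- lm(response[ok] ~ years[ok])
    vif <- NA_real_
  } else {
    stopifnot(length(covariate) == length(years))
    ok <- is.finite(years) & is.finite(response) & is.finite(covariate)
    if (sum(ok) < 4L) { insufficient$n_years <- sum(ok); return(insufficient) }
    r2 <- cor(years[ok], covariate[ok])^2
    if (isTRUE(all.equal(r2, 1)))
      stop("effort covariate is perfectly collinear with year", call. = FALSE)
    fit <- lm(response[ok] ~ years[ok] + covariate[ok])
    vif <- 1 / (1 - r2)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co[2L, 1L], se = co[2L, 2L], p = co[2L, 4L],
       adj_r2 = sm$adj.r.squared, vif = vif,
       n_years = sum(ok), status = "OK")
}

.latMetrics <- c("centroid_lat", "limit_N", "limit_S")
.lonMetrics <- c("centroid_lon", "limit_E", "limit_W")

#' Convert a degree-per-year slope to cumulative kilometres
#'
#' Multiplies the slope by the study span and the ground length of one
#' degree. Latitude metrics use `kmPerDegLat` directly; longitude metrics
#' are additionally scaled by `cos(referenceLat)` for meridian
#' convergence (a degree of longitude shortens toward the poles). The
#' sign of the slope is preserved, so southward/westward shifts come out
#' negative.
#'
#' @param slope trend slope in degrees/year.
#' @param metric one of `"centroid_lat"`, `"centroid_lon"`, `"limit_N"`,
#'   `"limit_S"`, `"limit_E"`, `"limit_W"`.
#' @param conv a [KmConversion-class].
#' @param referenceLat latitude (degrees) at which longitudinal degrees
#'   are measured; required for longitude metrics.
#' @param applyCos set `FALSE` to skip the meridian-convergence factor
#'   (degrees of longitude treated like degrees of latitude).
#' @return signed kilometres of cumulative change.
#' @export
toCumulativeKm <- function(slope, metric, conv = KmConversion(),
                           referenceLat = NA_real_, applyCos = TRUE) {
  stopifnot(is(conv, "KmConversion"))
  metric <- match.arg(metric, c(.latMetrics, .lonMetrics))
  km <- slope * conv@spanYears * conv@kmPerDegLat
  if (metric %in% .lonMetrics && applyCos) {
    if (!is.finite(referenceLat) || abs(referenceLat) >= 90)
      stop("longitude conversion needs a reference latitude with |lat| < 90",
           call. = FALSE)
    km <- km * cos(.deg2rad(referenceLat))
  }
  km
}

.metricColumns <- function(metric) {
  switch(metric,
    centroid_lat = c("det_centroid_lat", "effort_centroid_lat"),
    centroid_lon = c("det_centroid_lon", "effort_centroid_lon"),
    limit_N = c("det_max_lat", "effort_max_lat"),
    limit_S = c("det_min_lat", "effort_min_lat"),
    limit_E = c("det_max_lon", "effort_max_lon"),
    limit_W = c("det_min_lon", "effort_min_lon"))
}

.directionOf <- function(slope, metric) {
  if (!is.finite(slope) || slope == 0) return("")
  if (metric %in% .latMetrics) { if (slope > 0) "N" else "S" }
  else { if (slope > 0) "E" else "W" }
}

#' Fit all per-region trend regressions
#'
#' Runs the full trend battery over the annual summaries: for the
#' `full_range` region the four range limits plus both centroid axes;
#' for every other region the two centroid axes only. Each response is
#' paired with its like-for-like effort covariate. Slopes are converted
#' to cumulative kilometres over the configured span, using the region's
#' mean detection-centroid latitude as the reference latitude for
#' longitude metrics (or the fixed latitude, per the conversion policy).
#'
#' Failures in individual fits (insufficient years) are recorded in the
#' `status` column without aborting the batch. Any fit with VIF >= 10 is
#' flagged in the `high_vif` column.
#'
#' @param summaries annual summaries from [annualSummaries()].
#' @param conv a [KmConversion-class].
#' @param effortAdjusted set `FALSE` to drop the effort covariate (fits
#'   `position ~ year` only; mainly for studying the effort confound).
#' @param applyCos passed to [toCumulativeKm()].
#' @param alpha significance threshold for the `significant` column
#'   (default 0.05, two-sided, uncorrected).
#' @return a data.table with one row per region-metric: `region`,
#'   `metric`, `slope`, `se`, `p`, `adj_r2`, `vif`, `high_vif`,
#'   `n_years`, `cumulative_km`, `direction`, `significant`, `status`.
#' @export
runAllTrends <- function(summaries, conv = KmConversion(),
                         effortAdjusted = TRUE, applyCos = TRUE,
                         alpha = 0.05) {
  summaries <- as.data.table(summaries)
  regions <- unique(summaries$region)
  rows <- list()
  for (reg in regions) {
    sub <- summaries[region == reg]
    metrics <- if (reg == "full_range") c(.latMetrics, .lonMetrics)
               else c("centroid_lat", "centroid_lon")
    refLat <- if (conv@referenceLatPolicy == "fixed") conv@fixedReferenceLat
              else mean(sub$det_centroid_lat, na.rm = TRUE)
    for (m in metrics) {
      cols <- .metricColumns(m)
      ft <- fitTrend(sub$year, sub[[cols[1]]],
                     if (effortAdjusted) sub[[cols[2]]] else NULL)
      km <- if (ft$status == "OK")
        toCumulativeKm(ft$slope, m, conv, refLat, applyCos) else NA_real_
      rows[[length(rows) + 1L]] <- data.table(
        region = reg, metric = m, slope = ft$slope, se = ft$se, p = ft$p,
        adj_r2 = ft$adj_r2, vif = ft$vif,
        high_vif = is.finite(ft$vif) && ft$vif >= 10,
        n_years = ft$n_years, cumulative_km = km,
        direction = .directionOf(ft$slope, m),
        significant = is.finite(ft$p) && ft$p < alpha,
        status = ft$status)
    }
  }
  rbindlist(rows)
}

#' Write the trend results table
#'
#' Tab-separated, mirroring the usual report layout (region, metric, p,
#' adjusted R-squared, cumulative km and direction for significant rows)
#' plus the slope, standard error and VIF columns.
#'
#' @param trends result of [runAllTrends()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrends <- function(trends, path) {
  out <- copy(as.data.table(trends))
  out[, shift := ifelse(significant & is.finite(cumulative_km),
                        sprintf("%.0f km %s", abs(cumulative_km), direction),
                        "")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
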