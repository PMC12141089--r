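#' Generate synthetic EBD-style checklist tables with known drift
#'
#' Simulates a community-science observation process with known ground
#' truth so the whole pipeline is testable end to end. Checklist
#' locations are drawn from a mixture of Gaussian observer-effort
#' clusters whose centres drift at `effortDrift` degrees/year; the
#' species occupies a Gaussian kernel whose centre drifts at `occDrift`
#' degrees/year; detection on each checklist is Bernoulli with
#' probability `detectionP0 * exp(-d^2 / (2 * occSdKm^2))`, where `d` is
#' the distance (km, on the equal-area projected plane) from the
#' checklist to the year's occupancy centre.
#'
#' Contaminant checklists that the default filters must remove are
#' injected mutually exclusively: incidental protocol, incomplete,
#' traveling with distance > 5 km, or duration > 5 h. Their per-rule
#' counts are echoed in the returned truth record, so a filter exclusion
#' report can be compared against them exactly. Clean checklists are
#' always complete, within the distance and duration caps, and dated
#' inside the May-July window.
#'
#' One substream seed is derived per simulated year from the master
#' seed, so the stream for one year does not perturb the others.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param grid [GridSpec-class] whose projection defines the planar
#'   distance approximation.
#' @param speciesCode species code used in the observation table.
#' @return a list: `events` (sampling-event data.table), `observations`
#'   (observation data.table), `truth` (list echoing the imposed drifts,
#'   kernel, per-rule contaminant counts and seed).
#' @export
generateChecklists <- function(cfg = SyntheticConfig(), grid = GridSpec(),
                               speciesCode = "lobcur") {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  years <- seq(cfg@years[1], cfg@years[2])
  perYear <- vector("list", length(years))
  contaminants <- c(incidental = 0L, incomplete = 0L,
                    over_distance = 0L, over_duration = 0L)
  for (i in seq_along(years)) {
    yr <- years[i]
    set.seed(.substreamSeed(cfg@seed, i))
    py <- .simulateYear(cfg, grid, yr, i - 1L)
    contaminants <- contaminants + py$contaminants
    perYear[[i]] <- py$events
  }
  events <- rbindlist(perYear)
  observations <- events[detected == TRUE,
                         .(checklist_id, species_code = speciesCode, count)]
  events[, c("detected", "count") := NULL]
  truth <- list(
    years = as.integer(cfg@years),
    n_per_year = cfg@nPerYear,
    occupancy_center_0 = cfg@occCenter0,
    occupancy_drift_deg_per_year = cfg@occDrift,
    occupancy_sd_km = cfg@occSdKm,
    effort_drift_deg_per_year = cfg@effortDrift,
    detection_prob_at_center = cfg@detectionP0,
    contaminant_counts = as.list(contaminants),
    seed = cfg@seed)
  list(events = events[], observations = observations, truth = truth)
}

# deterministic per-year substream seed, kept inside 32-bit integer range
.substreamSeed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 104729) %% 2147483647)
}

.simulateYear <- function(cfg, grid, yr, t) {
  n <- cfg@nPerYear
  # contaminant category: 0 clean, 1 incidental, 2 incomplete,
  # 3 over-distance, 4 over-duration (mutually exclusive)
  fr <- c(cfg@fracIncidental, cfg@fracIncomplete,
          cfg@fracOverDistance, cfg@fracOverDuration)
  cat_ <- sample.int(5L, n, replace = TRUE,
                     prob = c(1 - sum(fr), fr)) - 1L
  ec <- cfg@effortCenters
  k <- sample.int(nrow(ec), n, replace = TRUE, prob = ec$weight)
  ctr <- projectPoints(grid,
                       ec$lon[k] + t * cfg@effortDrift[2],
                       ec$lat[k] + t * cfg@effortDrift[1])
  x <- ctr$x + rnorm(n, 0, ec$sdKm[k] * 1000)
  y <- ctr$y + rnorm(n, 0, ec$sdKm[k] * 1000)
  geo <- inverseProject(grid, x, y)
  occ <- projectPoints(grid,
                       cfg@occCenter0[2] + t * cfg@occDrift[2],
                       cfg@occCenter0[1] + t * cfg@occDrift[1])
  dKm <- sqrt((x - occ$x)^2 + (y - occ$y)^2) / 1000
  pDet <- cfg@detectionP0 * exp(-dKm^2 / (2 * cfg@occSdKm^2))
  detected <- rbinom(n, 1L, pDet) == 1L
  count <- rep(0L, n)
  nd <- sum(detected)
  if (nd) {
    cnt <- 1L + rpois(nd, 1.2)
    cnt[runif(nd) < 0.02] <- NA_integer_  # the "X" convention
    count[detected] <- cnt
  }
  protocol <- ifelse(runif(n) < cfg@pTraveling, "traveling", "stationary")
  protocol[cat_ == 1L] <- "incidental"
  protocol[cat_ == 3L] <- "traveling"      # over-distance must be traveling
  distance <- ifelse(protocol == "traveling", runif(n, 0.1, 5), NA_real_)
  distance[cat_ == 3L] <- runif(sum(cat_ == 3L), 5.01, 15)
  duration <- runif(n, 10, 300)
  duration[cat_ == 4L] <- runif(sum(cat_ == 4L), 301, 600)
  complete <- cat_ != 2L
  # random date in the May 1 - Jul 31 breeding window
  day0 <- as.Date(sprintf("%d-05-01", yr))
  dates <- day0 + sample.int(92L, n, replace = TRUE) - 1L
  events <- data.table(
    checklist_id = sprintf("S%d%06d", yr, seq_len(n)),
    group_id = NA_character_,
    protocol = protocol,
    date = dates,
    duration_minutes = round(duration, 1),
    distance_km = round(distance, 3),
    n_observers = 1L + rpois(n, 0.8),
    lat = geo$lat, lon = geo$lon,
    complete = complete,
    detected = detected, count = count)
  list(events = events,
       contaminants = c(incidental = sum(cat_ == 1L),
                        incomplete = sum(cat_ == 2L),
                        over_distance = sum(cat_ == 3L),
                        over_duration = sum(cat_ == 4L)))
}

#' Build a small named region fixture over the synthetic domain
#'
#' Stand-in region polygons (synthetic, not real conservation-region
#' boundaries) covering the simulated domain: either two side-by-side
#' rectangles or eight longitudinal bands mimicking an eight-region
#' stratification. Bands tile the domain without overlap; shared edges
#' are resolved by region order at assignment time.
#'
#' @param layout `"two_rectangles"` or `"eight_band"`.
#' @param path optional GeoJSON path to write the fixture to.
#' @param lonRange,latRange numeric pairs bounding the domain, degrees.
#' @return a [RegionSet-class] (written to `path` when given).
#' @export
makeRegionFixture <- function(layout = c("eight_band", "two_rectangles"),
                              path = NULL,
                              lonRange = c(-116, -104), latRange = c(40, 49.5)) {
  layout <- match.arg(layout)
  nBands <- if (layout == "two_rectangles") 2L else 8L
  cuts <- seq(lonRange[1], lonRange[2], length.out = nBands + 1L)
  nms <- if (nBands == 2L) c("west", "east") else sprintf("R%d", 1:8)
  polys <- lapply(seq_len(nBands), function(i) {
    cbind(lon = c(cuts[i], cuts[i + 1], cuts[i + 1], cuts[i]),
          lat = c(latRange[1], latRange[1], latRange[2], latRange[2]))
  })
  rs <- RegionSet(nms, polys)
  if (!is.null(path)) writeRegions(rs, path)
  rs
}

#' Observer-effort layout for studying the effort-drift confound
#'
#' A single broad effort cluster deliberately offset south of the default
#' occupancy centre. When this cluster drifts north while occupancy stays
#' put, the naive (uncorrected) centroid trend picks up a spurious
#' northward slope — sampling, not the species, is moving — which is
#' exactly the bias the effort covariate in [fitTrend()] is there to
#' absorb. The default lattice ([defaultEffortCenters()]) covers the
#' kernel too evenly to produce this bias.
#'
#' @return a data.frame with columns lat, lon, weight, sdKm.
#' @export
confoundEffortCenters <- function() {
  data.frame(lat = 43, lon = -110, weight = 1, sdKm = 150)
}

#' Run the full analysis in memory on one synthetic dataset
#'
#' Convenience wrapper chaining [generateChecklists()], [zeroFill()],
#' [applyFilters()], gridding, [annualSummaries()] and [runAllTrends()]
#' without touching disk; used heavily for replicate simulation studies.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param grid a [GridSpec-class].
#' @param regions a [RegionSet-class] (default: the eight-band fixture).
#' @param filterCfg a [FilterConfig-class].
#' @param conv a [KmConversion-class].
#' @param minYears retention threshold, years.
#' @param effortAdjusted passed to [runAllTrends()].
#' @return a list: `trends`, `summaries`, `report` (filter exclusions),
#'   `truth`, `nCells`.
#' @export
runSyntheticAnalysis <- function(cfg = SyntheticConfig(), grid = GridSpec(),
                                 regions = makeRegionFixture("eight_band"),
                                 filterCfg = FilterConfig(),
                                 conv = KmConversion(), minYears = 5L,
                                 effortAdjusted = TRUE) {
  sim <- generateChecklists(cfg, grid)
  fl <- applyFilters(zeroFill(sim$events, sim$observations), filterCfg)
  kept <- assignCells(fl$kept, grid)
  retained <- retainCells(cellYearCounts(kept), minYears)
  cym <- scoreCellYears(kept, retained, grid, regions,
                        years = seq(cfg@years[1], cfg@years[2]))
  summ <- annualSummaries(cym)
  list(trends = runAllTrends(summ, conv, effortAdjusted = effortAdjusted),
       summaries = summ, report = fl$report, truth = sim$truth,
       nCells = nrow(cym))
}
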