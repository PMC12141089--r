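#' @import methods
#' @importFrom stats coef cor lm pt rbinom rnorm rpois runif setNames
#' @importFrom utils head modifyList packageVersion
NULL

#' Equal-area analysis grid specification
#'
#' Defines the square analysis grid: cell size, the spherical Albers
#' equal-area conic projection it is built in, and the planar origin the
#' cell indices are anchored to. Cell membership is half-open,
#' `[x, x + cellSize) x [y, y + cellSize)`, so cells partition the plane.
#'
#' The default projection is a North America Albers parameterisation
#' (standard parallels 29.5 and 45.5 degrees N, origin 23 N / 96 W) on the
#' authalic sphere. An equal-area projection is required so that occupancy
#' scoring is not biased by latitude-dependent cell areas.
#'
#' @slot cellSize cell edge length in metres (default 10000).
#' @slot lat1,lat2 standard parallels, decimal degrees.
#' @slot lat0,lon0 projection origin, decimal degrees.
#' @slot radius sphere radius in metres (authalic radius by default).
#' @slot originX,originY planar coordinates of the grid anchor, metres.
#' @export
setClass("GridSpec",
  representation(cellSize = "numeric", lat1 = "numeric", lat2 = "numeric",
                 lat0 = "numeric", lon0 = "numeric", radius = "numeric",
                 originX = "numeric", originY = "numeric"),
  prototype(cellSize = 10000, lat1 = 29.5, lat2 = 45.5, lat0 = 23,
            lon0 = -96, radius = 6371007.2, originX = 0, originY = 0))

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (object@lat1 == -object@lat2)
    msgs <- c(msgs, "standard parallels must not be opposite (cone degenerates)")
  if (object@radius <= 0) msgs <- c(msgs, "radius must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridSpec
#'
#' @param cellSize cell edge length in metres.
#' @param lat1,lat2,lat0,lon0 projection parameters in decimal degrees.
#' @param radius sphere radius in metres.
#' @param originX,originY grid anchor in projected metres.
#' @return a [GridSpec-class] object.
#' @examples
#' g <- GridSpec()
#' cellSize(g)
#' @export
GridSpec <- function(cellSize = 10000, lat1 = 29.5, lat2 = 45.5,
                     lat0 = 23, lon0 = -96, radius = 6371007.2,
                     originX = 0, originY = 0) {
  new("GridSpec", cellSize = cellSize, lat1 = lat1, lat2 = lat2,
      lat0 = lat0, lon0 = lon0, radius = radius,
      originX = originX, originY = originY)
}

#' @describeIn GridSpec cell edge length in metres.
#' @param object,x a `GridSpec`.
#' @export
cellSize <- function(object) object@cellSize
gridLat1 <- function(object) object@lat1
gridLat2 <- function(object) object@lat2
gridLat0 <- function(object) object@lat0
gridLon0 <- function(object) object@lon0
gridRadius <- function(object) object@radius
gridOrigin <- function(object) c(x = object@originX, y = object@originY)

#' Projection identifier string for run metadata
#'
#' @param grid a [GridSpec-class].
#' @return a PROJ-style string describing the grid's projection.
#' @export
gridCRS <- function(grid) {
  sprintf("+proj=aea +lat_1=%g +lat_2=%g +lat_0=%g +lon_0=%g +R=%g +units=m",
          grid@lat1, grid@lat2, grid@lat0, grid@lon0, grid@radius)
}

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@cellSize / 1000, "km cells\n")
  cat("  projection:", gridCRS(object), "\n")
  cat("  origin: (", object@originX, ",", object@originY, ") m\n")
})

#' Checklist inclusion rules
#'
#' Encodes the quality filters applied to zero-filled checklists before
#' gridding: allowed protocols, maximum traveling distance and duration,
#' completeness, breeding-season window and study years. Thresholds are
#' boundary-inclusive for keeping (a 5.0 km traveling checklist is kept;
#' only strictly longer ones are dropped).
#'
#' @slot allowedProtocols character vector of protocol names kept.
#' @slot maxDistanceKm maximum traveling distance in km (default 5).
#' @slot maxDurationHours maximum checklist duration in hours (default 5).
#' @slot requireComplete drop incomplete checklists (default TRUE).
#' @slot seasonStart,seasonEnd month-day strings "MM-DD" (default May 1 to
#'   Jul 31, the breeding window).
#' @slot yearRange inclusive first and last study year (default 2010-2022).
#' @export
setClass("FilterConfig",
  representation(allowedProtocols = "character", maxDistanceKm = "numeric",
                 maxDurationHours = "numeric", requireComplete = "logical",
                 seasonStart = "character", seasonEnd = "character",
                 yearRange = "integer"),
  prototype(allowedProtocols = c("stationary", "traveling"),
            maxDistanceKm = 5, maxDurationHours = 5, requireComplete = TRUE,
            seasonStart = "05-01", seasonEnd = "07-31",
            yearRange = c(2010L, 2022L)))

.mdOK <- function(md) grepl("^[01][0-9]-[0-3][0-9]$", md)

setValidity("FilterConfig", function(object) {
  msgs <- character()
  if (object@maxDistanceKm <= 0) msgs <- c(msgs, "maxDistanceKm must be > 0")
  if (object@maxDurationHours <= 0) msgs <- c(msgs, "maxDurationHours must be > 0")
  if (!.mdOK(object@seasonStart) || !.mdOK(object@seasonEnd))
    msgs <- c(msgs, "season bounds must be 'MM-DD' strings")
  else if (object@seasonStart > object@seasonEnd)
    msgs <- c(msgs, "seasonStart must not be after seasonEnd")
  if (length(object@yearRange) != 2 || object@yearRange[1] > object@yearRange[2])
    msgs <- c(msgs, "yearRange must be an ordered pair of years")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FilterConfig
#'
#' @param allowedProtocols protocols kept (default stationary + traveling).
#' @param maxDistanceKm,maxDurationHours effort caps (keep if <=).
#' @param requireComplete drop incomplete checklists.
#' @param seasonStart,seasonEnd "MM-DD" breeding-season window.
#' @param yearRange inclusive year pair.
#' @return a [FilterConfig-class] object.
#' @export
FilterConfig <- function(allowedProtocols = c("stationary", "traveling"),
                         maxDistanceKm = 5, maxDurationHours = 5,
                         requireComplete = TRUE,
                         seasonStart = "05-01", seasonEnd = "07-31",
                         yearRange = c(2010L, 2022L)) {
  new("FilterConfig", allowedProtocols = allowedProtocols,
      maxDistanceKm = maxDistanceKm, maxDurationHours = maxDurationHours,
      requireComplete = requireComplete, seasonStart = seasonStart,
      seasonEnd = seasonEnd, yearRange = as.integer(yearRange))
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n")
  cat("  protocols:", paste(object@allowedProtocols, collapse = ", "), "\n")
  cat("  distance <=", object@maxDistanceKm, "km; duration <=",
      object@maxDurationHours, "h; complete only:", object@requireComplete, "\n")
  cat("  season:", object@seasonStart, "to", object@seasonEnd,
      "; years:", object@yearRange[1], "-", object@yearRange[2], "\n")
})

#' Degree-to-kilometre conversion policy
#'
#' Governs how a fitted trend slope in degrees per year is converted to a
#' cumulative ground distance. Latitude trends use a fixed kilometres per
#' degree of latitude; longitude trends are additionally shrunk by
#' `cos(reference latitude)` for meridian convergence.
#'
#' @slot kmPerDegLat kilometres per degree of latitude (default 111.32,
#'   the spherical mean).
#' @slot spanYears number of years the cumulative change is accumulated
#'   over (default 13, the inclusive 2010-2022 count; set to the interval
#'   count, e.g. 12, for an endpoints-difference policy).
#' @slot referenceLatPolicy `"region_mean_centroid_lat"` (use the mean
#'   detection-centroid latitude of the region) or `"fixed"`.
#' @slot fixedReferenceLat latitude used when the policy is `"fixed"`.
#' @export
setClass("KmConversion",
  representation(kmPerDegLat = "numeric", spanYears = "numeric",
                 referenceLatPolicy = "character",
                 fixedReferenceLat = "numeric"),
  prototype(kmPerDegLat = 111.32, spanYears = 13,
            referenceLatPolicy = "region_mean_centroid_lat",
            fixedReferenceLat = NA_real_))

setValidity("KmConversion", function(object) {
  msgs <- character()
  if (object@kmPerDegLat <= 0) msgs <- c(msgs, "kmPerDegLat must be > 0")
  if (object@spanYears < 2) msgs <- c(msgs, "spanYears must be >= 2")
  if (!object@referenceLatPolicy %in% c("region_mean_centroid_lat", "fixed"))
    msgs <- c(msgs, "unknown referenceLatPolicy")
  if (object@referenceLatPolicy == "fixed" &&
      (!is.finite(object@fixedReferenceLat) ||
       abs(object@fixedReferenceLat) >= 90))
    msgs <- c(msgs, "fixedReferenceLat must be finite and |lat| < 90")
  if (length(msgs)) msgs else TRUE
})

#' Construct a KmConversion
#'
#' @param kmPerDegLat kilometres per degree of latitude.
#' @param spanYears years of accumulated change.
#' @param referenceLatPolicy see [KmConversion-class].
#' @param fixedReferenceLat latitude for the `"fixed"` policy.
#' @return a [KmConversion-class] object.
#' @export
KmConversion <- function(kmPerDegLat = 111.32, spanYears = 13,
                         referenceLatPolicy = "region_mean_centroid_lat",
                         fixedReferenceLat = NA_real_) {
  new("KmConversion", kmPerDegLat = kmPerDegLat, spanYears = spanYears,
      referenceLatPolicy = referenceLatPolicy,
      fixedReferenceLat = fixedReferenceLat)
}

setMethod("show", "KmConversion", function(object) {
  cat("KmConversion:", object@kmPerDegLat, "km/deg lat over",
      object@spanYears, "years; reference latitude:",
      object@referenceLatPolicy, "\n")
})

#' Named analysis regions (polygon set)
#'
#' A small container for named region polygons in geographic coordinates,
#' e.g. Bird Conservation Region boundaries. The union of all regions acts
#' as an implicit full-range region. Polygons are stored as two-column
#' lon/lat matrices (outer rings, unclosed); ties at shared boundaries are
#' broken by storage order.
#'
#' @slot regionNames character vector of region names, in priority order.
#' @slot polygons list of numeric matrices with columns lon, lat.
#' @export
setClass("RegionSet",
  representation(regionNames = "character", polygons = "list"))

setValidity("RegionSet", function(object) {
  msgs <- character()
  if (length(object@regionNames) != length(object@polygons))
    msgs <- c(msgs, "one polygon per region name required")
  if (anyDuplicated(object@regionNames))
    msgs <- c(msgs, "region names must be unique")
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || !all(is.finite(p)))
      msgs <- c(msgs, sprintf("polygon %d must be a finite n x 2 matrix, n >= 3", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionSet
#'
#' Polygons are repaired on construction: consecutive duplicate vertices are
#' dropped and an explicit closing vertex, if present, is removed.
#'
#' @param regionNames character names, one per polygon.
#' @param polygons list of two-column lon/lat matrices.
#' @return a [RegionSet-class] object.
#' @export
RegionSet <- function(regionNames, polygons) {
  polygons <- lapply(polygons, .repairRing)
  new("RegionSet", regionNames = as.character(regionNames),
      polygons = polygons)
}

# drop explicit closure and consecutive duplicates
.repairRing <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  unname(p[keep, , drop = FALSE])
}

#' @describeIn RegionSet region names in priority order.
#' @param object a `RegionSet`.
#' @export
regionNames <- function(object) object@regionNames

#' @describeIn RegionSet list of lon/lat polygon matrices.
#' @export
regionPolygons <- function(object) setNames(object@polygons, object@regionNames)

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet with", length(object@regionNames), "regions:",
      paste(object@regionNames, collapse = ", "), "\n")
})

setMethod("length", "RegionSet", function(x) length(x@regionNames))

#' Synthetic checklist generator configuration
#'
#' Parameters of the simulated observation process: a mixture of Gaussian
#' observer-effort clusters whose centres may drift over years, and a
#' Gaussian species occupancy kernel whose centre may drift independently.
#' Detection on a checklist is Bernoulli with probability
#' `detectionP0 * exp(-d^2 / (2 * occSdKm^2))`, `d` the planar distance to
#' the year's occupancy centre. Contaminant checklists (incidental
#' protocol, incomplete, over-distance, over-duration) are injected at the
#' configured fractions, mutually exclusively, so a downstream exclusion
#' report can be checked against the injected counts exactly.
#'
#' @slot years inclusive first and last simulated year.
#' @slot nPerYear checklists simulated per year.
#' @slot effortCenters data.frame with columns lat, lon, weight, sdKm.
#' @slot effortDrift,occDrift degrees/year drift (lat, lon).
#' @slot occCenter0 occupancy kernel centre in year 1 (lat, lon).
#' @slot occSdKm occupancy kernel standard deviation, km.
#' @slot detectionP0 detection probability at the kernel centre.
#' @slot pTraveling probability a clean checklist is traveling protocol.
#' @slot fracIncomplete,fracIncidental,fracOverDistance,fracOverDuration
#'   contaminant fractions.
#' @slot seed master seed; per-year substreams are derived from it.
#' @export
setClass("SyntheticConfig",
  representation(years = "integer", nPerYear = "integer",
                 effortCenters = "data.frame", effortDrift = "numeric",
                 occCenter0 = "numeric", occDrift = "numeric",
                 occSdKm = "numeric", detectionP0 = "numeric",
                 pTraveling = "numeric", fracIncomplete = "numeric",
                 fracIncidental = "numeric", fracOverDistance = "numeric",
                 fracOverDuration = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  probs <- c(pTraveling = object@pTraveling,
             fracIncomplete = object@fracIncomplete,
             fracIncidental = object@fracIncidental,
             fracOverDistance = object@fracOverDistance,
             fracOverDuration = object@fracOverDuration)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) msgs <- c(msgs, paste("fields out of [0,1]:",
                                         paste(bad, collapse = ", ")))
  fr <- object@fracIncomplete + object@fracIncidental +
    object@fracOverDistance + object@fracOverDuration
  if (fr >= 1) msgs <- c(msgs, "contaminant fractions must sum to < 1")
  if (object@detectionP0 < 0 || object@detectionP0 > 1)
    msgs <- c(msgs, "detectionP0 must be in [0, 1]")
  if (object@occSdKm <= 0) msgs <- c(msgs, "occSdKm must be > 0")
  ec <- object@effortCenters
  need <- c("lat", "lon", "weight", "sdKm")
  if (!all(need %in% names(ec)))
    msgs <- c(msgs, paste("effortCenters needs columns:",
                          paste(need, collapse = ", ")))
  else if (any(ec$sdKm <= 0) || any(ec$weight < 0) || sum(ec$weight) <= 0)
    msgs <- c(msgs, "effortCenters: sdKm > 0, weights >= 0, weight sum > 0")
  if (length(object@years) != 2 || object@years[1] > object@years[2])
    msgs <- c(msgs, "years must be an ordered pair")
  if (object@nPerYear < 1) msgs <- c(msgs, "nPerYear must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults emulate the scale of a 13-year community-science extract for a
#' wide-ranging grassland shorebird of western North America: 3300
#' checklists per year (42,900 total) over a broad, evenly covered
#' sampling window, with a compact (100 km sd) occupancy kernel whose
#' whole drift trajectory stays inside the well-sampled window, and a
#' detection probability of 0.6 at the kernel centre. Both drifts are
#' zero by default.
#'
#' @param years inclusive year pair.
#' @param nPerYear checklists per year.
#' @param effortCenters data.frame(lat, lon, weight, sdKm).
#' @param effortDrift,occDrift c(lat, lon) degrees/year.
#' @param occCenter0 c(lat, lon) occupancy centre in the first year.
#' @param occSdKm occupancy kernel sd, km.
#' @param detectionP0 detection probability at kernel centre.
#' @param pTraveling traveling-protocol probability for clean checklists.
#' @param fracIncomplete,fracIncidental,fracOverDistance,fracOverDuration
#'   contaminant fractions.
#' @param seed master seed.
#' @return a [SyntheticConfig-class] object.
#' @export
SyntheticConfig <- function(years = c(2010L, 2022L), nPerYear = 3300L,
                            effortCenters = defaultEffortCenters(),
                            effortDrift = c(0, 0),
                            occCenter0 = c(44.2, -110),
                            occDrift = c(0, 0), occSdKm = 100,
                            detectionP0 = 0.6, pTraveling = 0.55,
                            fracIncomplete = 0.08, fracIncidental = 0.05,
                            fracOverDistance = 0.04, fracOverDuration = 0.03,
                            seed = 1L) {
  new("SyntheticConfig", years = as.integer(years),
      nPerYear = as.integer(nPerYear), effortCenters = effortCenters,
      effortDrift = as.numeric(effortDrift),
      occCenter0 = as.numeric(occCenter0), occDrift = as.numeric(occDrift),
      occSdKm = occSdKm, detectionP0 = detectionP0, pTraveling = pTraveling,
      fracIncomplete = fracIncomplete, fracIncidental = fracIncidental,
      fracOverDistance = fracOverDistance, fracOverDuration = fracOverDuration,
      seed = as.integer(seed))
}

#' Default observer-effort clusters for the synthetic generator
#'
#' A 4 x 4 lattice of broad (150 km sd) Gaussian clusters over the
#' simulated breeding core (roughly the intermountain west), overlapping
#' enough that their mixture is near-uniform across the central window.
#' Broad, even coverage keeps per-cell sampling rates high enough for the
#' five-year retention rule while leaving the detected-range centroid
#' identifiable: strong small-scale effort gradients would attenuate any
#' imposed occupancy drift toward the static effort surface.
#'
#' @return a data.frame with columns lat, lon, weight, sdKm.
#' @export
defaultEffortCenters <- function() {
  grid <- expand.grid(lat = seq(41.5, 48, length.out = 4),
                      lon = seq(-114, -106, length.out = 4))
  data.frame(lat = grid$lat, lon = grid$lon, weight = 1 / 16, sdKm = 150)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@years[1], "-", object@years[2], ",",
      object@nPerYear, "checklists/year\n")
  cat("  occupancy: centre (", object@occCenter0[1], ",", object@occCenter0[2],
      "), sd", object@occSdKm, "km, drift (", object@occDrift[1], ",",
      object@occDrift[2], ") deg/yr\n")
  cat("  effort:", nrow(object@effortCenters), "clusters, drift (",
      object@effortDrift[1], ",", object@effortDrift[2], ") deg/yr\n")
  cat("  contaminants: incomplete", object@fracIncomplete, ", incidental",
      object@fracIncidental, ", over-distance", object@fracOverDistance,
      ", over-duration", object@fracOverDuration, "\n")
  cat("  seed:", object@seed, "\n")
})
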