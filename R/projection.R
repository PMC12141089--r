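# Spherical Albers equal-area conic (Snyder 1987, eqs 14-1 to 14-11).
# All angles in radians internally; exported interfaces take decimal degrees.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.albersConstants <- function(grid) {
  p1 <- .deg2rad(gridLat1(grid))
  p2 <- .deg2rad(gridLat2(grid))
  p0 <- .deg2rad(gridLat0(grid))
  n <- (sin(p1) + sin(p2)) / 2
  C <- cos(p1)^2 + 2 * n * sin(p1)
  rho0 <- gridRadius(grid) * sqrt(C - 2 * n * sin(p0)) / n
  list(n = n, C = C, rho0 = rho0)
}

#' Project geographic coordinates to the grid's equal-area plane
#'
#' Forward spherical Albers equal-area conic projection onto the plane the
#' analysis grid lives in. Equal-area by construction, so every grid cell
#' covers the same ground area regardless of latitude.
#'
#' @param grid a [GridSpec-class] object.
#' @param lon,lat numeric vectors of decimal degrees (WGS84, lon in
#'   \[-180, 180\]).
#' @return a data.frame with columns `x`, `y` in metres.
#' @seealso [inverseProject()] for the inverse transform.
#' @export
projectPoints <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  bad <- !is.finite(lon) | !is.finite(lat) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    stop("coordinates failing projection at positions: ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  k <- .albersConstants(grid)
  R <- gridRadius(grid)
  phi <- .deg2rad(lat)
  theta <- k$n * (.deg2rad(lon) - .deg2rad(gridLon0(grid)))
  rho <- R * sqrt(k$C - 2 * k$n * sin(phi)) / k$n
  data.frame(x = rho * sin(theta), y = k$rho0 - rho * cos(theta))
}

#' Inverse-project planar coordinates back to geographic degrees
#'
#' @param grid a [GridSpec-class] object.
#' @param x,y numeric vectors of projected metres.
#' @return a data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
inverseProject <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  k <- .albersConstants(grid)
  R <- gridRadius(grid)
  rho <- sqrt(x^2 + (k$rho0 - y)^2)
  theta <- atan2(x, k$rho0 - y)
  s <- (k$C - (rho * k$n / R)^2) / (2 * k$n)
  # clamp against rounding just outside [-1, 1]
  s <- pmin(1, pmax(-1, s))
  data.frame(lon = gridLon0(grid) + .rad2deg(theta / k$n),
             lat = .rad2deg(asin(s)))
}
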