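#' Corner coordinates of grid cells in the projected plane
#'
#' @param cells data.frame with `cell_col`, `cell_row`.
#' @param grid a [GridSpec-class].
#' @return a data.table with one row per corner: `cell`, `x`, `y`
#'   (4 corners per cell, counter-clockwise from the lower-left).
#' @export
cellCorners <- function(cells, grid = GridSpec()) {
  cells <- as.data.table(cells)
  cs <- cellSize(grid)
  org <- gridOrigin(grid)
  x0 <- org["x"] + cells$cell_col * cs
  y0 <- org["y"] + cells$cell_row * cs
  n <- nrow(cells)
  data.table(cell = rep(seq_len(n), each = 4L),
             x = as.vector(rbind(x0, x0 + cs, x0 + cs, x0)),
             y = as.vector(rbind(y0, y0, y0 + cs, y0 + cs)))
}

# Shoelace area and centroid of one closed ring given as unclosed
# vertices. Computed in vertex-local coordinates: at continental
# magnitudes (1e6-1e7 m) the raw shoelace products cancel catastrophically
# and the centroid picks up metre-scale noise.
.polygonAreaCentroid <- function(x, y) {
  x0 <- x[1L]
  y0 <- y[1L]
  x <- x - x0
  y <- y - y0
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  list(area = A,
       cx = x0 + sum((x + xn) * cross) / (6 * A),
       cy = y0 + sum((y + yn) * cross) / (6 * A))
}

#' Centroid of the union of grid cells, in geographic degrees
#'
#' Computes the area-weighted centroid of the union of the given cells in
#' the equal-area projected plane and transforms it to geographic
#' coordinates. Because cell membership is half-open the cells partition
#' the plane and never overlap, so the union centroid is the area-weighted
#' combination of the per-cell polygon centroids (all areas equal); it is
#' evaluated here per cell by the shoelace formula and then combined.
#'
#' @param cells data.frame of `cell_col`, `cell_row` (distinct cells).
#' @param grid a [GridSpec-class].
#' @return named numeric `c(lat, lon)`; both `NA` for an empty cell set
#'   (the explicit EMPTY result — callers skip such region-years).
#' @export
unionCentroid <- function(cells, grid = GridSpec()) {
  cells <- unique(as.data.table(cells)[, .(cell_col, cell_row)])
  if (!nrow(cells)) return(c(lat = NA_real_, lon = NA_real_))
  corners <- cellCorners(cells, grid)
  agg <- corners[, {
    pc <- .polygonAreaCentroid(x, y)
    list(area = abs(pc$area), cx = pc$cx, cy = pc$cy)
  }, by = cell]
  W <- sum(agg$area)
  geo <- inverseProject(grid, sum(agg$area * agg$cx) / W,
                        sum(agg$area * agg$cy) / W)
  c(lat = geo$lat, lon = geo$lon)
}

#' Geographic bounding box around grid cells
#'
#' Transforms every cell corner to geographic degrees and takes the
#' coordinate extremes, so the bounds trace the cell edges rather than
#' the cell centres.
#'
#' @param cells data.frame of `cell_col`, `cell_row`.
#' @param grid a [GridSpec-class].
#' @return named numeric `c(min_lat, max_lat, min_lon, max_lon)`; all
#'   `NA` for an empty cell set.
#' @export
boundsOf <- function(cells, grid = GridSpec()) {
  cells <- unique(as.data.table(cells)[, .(cell_col, cell_row)])
  if (!nrow(cells))
    return(c(min_lat = NA_real_, max_lat = NA_real_,
             min_lon = NA_real_, max_lon = NA_real_))
  corners <- cellCorners(cells, grid)
  geo <- inverseProject(grid, corners$x, corners$y)
  c(min_lat = min(geo$lat), max_lat = max(geo$lat),
    min_lon = min(geo$lon), max_lon = max(geo$lon))
}

#' Per-region annual range metrics
#'
#' For every region (each named region plus the implicit `full_range`
#' union of all regions) and every study year, computes the detection
#' metrics over cells with at least one detection and the matching
#' observer-effort metrics over cells with at least one checklist:
#' union-of-cells centroids and bounding-box range limits. Effort metrics
#' are computed from the same retained grid cells as the detection
#' metrics, so the downstream trend covariate is like-for-like.
#'
#' Region-years with no detection cells carry `NA` detection metrics (the
#' EMPTY encoding); effort metrics are present whenever any cell was
#' sampled.
#'
#' @param cym a [CellYearMatrix-class] whose rowData has a `region`
#'   column (see [scoreCellYears()]).
#' @return a data.table with one row per region-year: cell counts,
#'   `det_centroid_lat/lon`, `det_min/max_lat/lon`, and the same for
#'   `effort_`.
#' @export
annualSummaries <- function(cym) {
  stopifnot(is(cym, "CellYearMatrix"))
  rd <- rowData(cym)
  if (!"region" %in% names(rd))
    stop("scoreCellYears() must be run with a RegionSet so cells carry regions",
         call. = FALSE)
  grid <- metadata(cym)$grid
  years <- yearsOf(cym)
  det <- detectionCounts(cym) >= 1
  eff <- checklistCounts(cym) >= 1
  regs <- as.character(rd$region)
  regionList <- c(list(full_range = !is.na(regs)),
                  lapply(setNames(nm = unique(regs[!is.na(regs)])),
                         function(r) !is.na(regs) & regs == r))
  geom <- .cellGeometry(rd, grid)
  out <- vector("list", length(regionList) * length(years))
  k <- 0L
  for (rname in names(regionList)) {
    inReg <- regionList[[rname]]
    for (j in seq_along(years)) {
      effIdx <- which(inReg & eff[, j])
      if (!length(effIdx)) next
      detIdx <- which(inReg & det[, j])
      dC <- .fastCentroid(geom, detIdx, grid)
      eC <- .fastCentroid(geom, effIdx, grid)
      k <- k + 1L
      out[[k]] <- data.table(
        region = rname, year = years[j],
        n_det_cells = length(detIdx), n_effort_cells = length(effIdx),
        det_centroid_lat = dC[2], det_centroid_lon = dC[1],
        det_min_lat = .aggOrNA(geom$cornerMinLat, detIdx, min),
        det_max_lat = .aggOrNA(geom$cornerMaxLat, detIdx, max),
        det_min_lon = .aggOrNA(geom$cornerMinLon, detIdx, min),
        det_max_lon = .aggOrNA(geom$cornerMaxLon, detIdx, max),
        effort_centroid_lat = eC[2], effort_centroid_lon = eC[1],
        effort_min_lat = .aggOrNA(geom$cornerMinLat, effIdx, min),
        effort_max_lat = .aggOrNA(geom$cornerMaxLat, effIdx, max),
        effort_min_lon = .aggOrNA(geom$cornerMinLon, effIdx, min),
        effort_max_lon = .aggOrNA(geom$cornerMaxLon, effIdx, max))
    }
  }
  rbindlist(out[seq_len(k)])
}

# Per-cell geometry, computed once per CellYearMatrix: shoelace area and
# centroid of each cell polygon in projected space, and the geographic
# extremes of each cell's corners. The region-year loop then only
# aggregates; the aggregate equals unionCentroid()/boundsOf() on the same
# cell subset because the cells are disjoint (half-open partition).
.cellGeometry <- function(rd, grid) {
  cells <- data.table(cell_col = rd$cellCol, cell_row = rd$cellRow)
  corners <- cellCorners(cells, grid)
  pc <- corners[, {
    g <- .polygonAreaCentroid(x, y)
    list(area = abs(g$area), cx = g$cx, cy = g$cy)
  }, by = cell]
  geo <- inverseProject(grid, corners$x, corners$y)
  cornerLat <- matrix(geo$lat, ncol = 4L, byrow = TRUE)
  cornerLon <- matrix(geo$lon, ncol = 4L, byrow = TRUE)
  list(area = pc$area, cx = pc$cx, cy = pc$cy,
       cornerMinLat = do.call(pmin, as.data.frame(cornerLat)),
       cornerMaxLat = do.call(pmax, as.data.frame(cornerLat)),
       cornerMinLon = do.call(pmin, as.data.frame(cornerLon)),
       cornerMaxLon = do.call(pmax, as.data.frame(cornerLon)))
}

.fastCentroid <- function(geom, idx, grid) {
  if (!length(idx)) return(c(NA_real_, NA_real_))
  W <- sum(geom$area[idx])
  g <- inverseProject(grid, sum(geom$area[idx] * geom$cx[idx]) / W,
                      sum(geom$area[idx] * geom$cy[idx]) / W)
  c(g$lon, g$lat)
}

.aggOrNA <- function(v, idx, f) if (length(idx)) f(v[idx]) else NA_real_
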