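#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Cell-by-year detection and effort count matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass holding, for every retained grid cell (rows) and study year
#' (columns), the number of checklists (`checklists` assay) and the number
#' of checklists with a detection (`detections` assay). Row metadata
#' carries the cell indices, projected and geographic cell centres, and
#' (optionally) the region each cell centre falls in; the
#' [GridSpec-class] used to build the grid is stored in `metadata()$grid`.
#'
#' A cell-year counts as a detection cell-year iff `detections >= 1`, and
#' as an effort cell-year iff `checklists >= 1`.
#'
#' @export
setClass("CellYearMatrix", contains = "SummarizedExperiment")

setValidity("CellYearMatrix", function(object) {
  msgs <- character()
  an <- assayNames(object)
  if (!all(c("checklists", "detections") %in% an))
    return("assays 'checklists' and 'detections' are required")
  ck <- assay(object, "checklists")
  dt <- assay(object, "detections")
  if (any(ck < 0) || any(dt < 0)) msgs <- c(msgs, "counts must be nonnegative")
  if (any(dt > ck))
    msgs <- c(msgs, "detections cannot exceed checklists in any cell-year")
  need <- c("cellCol", "cellRow", "centerLon", "centerLat")
  if (!all(need %in% names(rowData(object))))
    msgs <- c(msgs, paste("rowData needs columns:", paste(need, collapse = ", ")))
  if (!is(metadata(object)$grid, "GridSpec"))
    msgs <- c(msgs, "metadata()$grid must be a GridSpec")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CellYearMatrix checklist-count matrix (cells x years).
#' @param x a `CellYearMatrix`.
#' @export
checklistCounts <- function(x) assay(x, "checklists")

#' @describeIn CellYearMatrix detection-count matrix (cells x years).
#' @export
detectionCounts <- function(x) assay(x, "detections")

#' @describeIn CellYearMatrix logical matrix: was the species detected in
#'   the cell-year.
#' @export
detectedIn <- function(x) detectionCounts(x) >= 1

#' @describeIn CellYearMatrix integer vector of study years (columns).
#' @export
yearsOf <- function(x) as.integer(colnames(x))

setMethod("show", "CellYearMatrix", function(object) {
  callNextMethod()
  ndet <- sum(detectionCounts(object) >= 1)
  neff <- sum(checklistCounts(object) >= 1)
  cat(sprintf("detection cell-years: %d of %d sampled cell-years\n",
              ndet, neff))
})

#' Assign checklists to equal-area grid cells
#'
#' Projects checklist coordinates into the grid's equal-area plane and
#' computes half-open cell indices
#' `cell_col = floor((x - originX) / cellSize)` (and likewise rows), so
#' that the cells partition the plane: a point exactly on a cell's
#' right/top edge belongs to the next cell.
#'
#' @param records checklist records with `lon`, `lat` columns.
#' @param grid a [GridSpec-class].
#' @return the records with `cell_col`, `cell_row` and `year` columns
#'   added.
#' @export
assignCells <- function(records, grid = GridSpec()) {
  records <- as.data.table(records)
  xy <- projectPoints(grid, records$lon, records$lat)
  cs <- cellSize(grid)
  org <- gridOrigin(grid)
  records[, `:=`(cell_col = floor((xy$x - org["x"]) / cs),
                 cell_row = floor((xy$y - org["y"]) / cs))]
  if (!"year" %in% names(records))
    records[, year := as.integer(format(date, "%Y"))]
  records[]
}

#' Summarise checklist and detection counts per cell-year
#'
#' @param records cell-assigned checklist records ([assignCells()]).
#' @return a data.table with one row per sampled cell-year: `cell_col`,
#'   `cell_row`, `year`, `n_checklists`, `n_detections`.
#' @export
cellYearCounts <- function(records) {
  records <- as.data.table(records)
  records[, .(n_checklists = .N, n_detections = sum(detected)),
          by = .(cell_col, cell_row, year)]
}

#' Retain grid cells sampled in enough distinct years
#'
#' A cell is retained iff it has at least one checklist in at least
#' `minYears` distinct years, which screens out cells too poorly sampled
#' to contribute to a trend. Retention counts years with any checklist,
#' not years with detections.
#'
#' @param summaries cell-year counts from [cellYearCounts()].
#' @param minYears minimum number of distinct sampled years (default 5).
#' @return a data.table of retained `cell_col`, `cell_row` pairs.
#' @export
retainCells <- function(summaries, minYears = 5L) {
  summaries <- as.data.table(summaries)
  ny <- summaries[n_checklists >= 1L,
                  .(n_years = uniqueN(year)), by = .(cell_col, cell_row)]
  ny[n_years >= minYears, .(cell_col, cell_row)]
}

#' Score retained cells by detection in each year
#'
#' Builds the [CellYearMatrix-class] for the retained cells over the full
#' study period. Years with no checklist in a cell have zero counts in
#' both assays (and therefore count as neither effort nor detection
#' cell-years).
#'
#' @param records cell-assigned, filtered checklist records.
#' @param retained retained cells from [retainCells()].
#' @param grid the [GridSpec-class] used for assignment.
#' @param regions optional [RegionSet-class]; when supplied each cell is
#'   assigned to the region containing its centre point.
#' @param years optional integer vector of study years (defaults to the
#'   range present in `records`).
#' @return a [CellYearMatrix-class].
#' @export
scoreCellYears <- function(records, retained, grid = GridSpec(),
                           regions = NULL, years = NULL) {
  counts <- cellYearCounts(records)
  counts <- merge(counts, as.data.table(retained),
                  by = c("cell_col", "cell_row"))
  if (is.null(years))
    years <- seq(min(counts$year), max(counts$year))
  cells <- unique(counts[, .(cell_col, cell_row)])
  setorder(cells, cell_col, cell_row)
  cellKey <- paste(cells$cell_col, cells$cell_row, sep = ":")
  ck <- matrix(0L, nrow(cells), length(years),
               dimnames = list(cellKey, years))
  de <- ck
  i <- match(paste(counts$cell_col, counts$cell_row, sep = ":"), cellKey)
  j <- match(counts$year, years)
  ok <- !is.na(j)
  ck[cbind(i[ok], j[ok])] <- counts$n_checklists[ok]
  de[cbind(i[ok], j[ok])] <- as.integer(counts$n_detections[ok])
  cs <- cellSize(grid)
  org <- gridOrigin(grid)
  cx <- org["x"] + (cells$cell_col + 0.5) * cs
  cy <- org["y"] + (cells$cell_row + 0.5) * cs
  geo <- inverseProject(grid, cx, cy)
  rd <- DataFrame(cellCol = cells$cell_col, cellRow = cells$cell_row,
                  centerX = cx, centerY = cy,
                  centerLon = geo$lon, centerLat = geo$lat)
  if (!is.null(regions))
    rd$region <- assignRegion(geo$lon, geo$lat, regions)
  se <- SummarizedExperiment(
    assays = list(checklists = ck, detections = de), rowData = rd,
    metadata = list(grid = grid))
  new("CellYearMatrix", se)
}

#' Assign points to named regions
#'
#' Each point is assigned to the first region (in the RegionSet's storage
#' order) whose polygon contains it, which makes assignment deterministic
#' at shared boundaries. Points outside every polygon get `NA`.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param regions a [RegionSet-class].
#' @return character vector of region names (`NA` = outside all regions).
#' @export
assignRegion <- function(lon, lat, regions) {
  stopifnot(is(regions, "RegionSet"))
  out <- rep(NA_character_, length(lon))
  pts <- cbind(lon, lat)
  todo <- which(rep(TRUE, length(lon)))
  for (i in seq_along(regions@polygons)) {
    if (!length(todo)) break
    ring <- regions@polygons[[i]]
    ring <- rbind(ring, ring[1L, , drop = FALSE])
    inside <- mgcv::in.out(ring, pts[todo, , drop = FALSE])
    out[todo[inside]] <- regions@regionNames[i]
    todo <- todo[!inside]
  }
  out
}
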