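cellsDT <- function(...) data.table::data.table(...)

test_that("union centroid of one or two cells is exact", {
  g <- GridSpec()
  one <- cellsDT(cell_col = -100L, cell_row = 250L)
  got <- unionCentroid(one, g)
  ctr <- inverseProject(g, (-100 + 0.5) * 1e4, (250 + 0.5) * 1e4)
  expect_equal(unname(got["lat"]), ctr$lat, tolerance = 1e-12)
  expect_equal(unname(got["lon"]), ctr$lon, tolerance = 1e-12)
  # two disjoint equal cells: midpoint of the two centres
  two <- cellsDT(cell_col = c(-100L, -90L), cell_row = c(250L, 260L))
  got2 <- unionCentroid(two, g)
  mid <- inverseProject(g, (-95 + 0.5) * 1e4, (255 + 0.5) * 1e4)
  expect_equal(unname(got2["lat"]), mid$lat, tolerance = 1e-12)
  expect_equal(unname(got2["lon"]), mid$lon, tolerance = 1e-12)
  # empty set: the explicit EMPTY encoding
  expect_true(all(is.na(unionCentroid(cellsDT(cell_col = integer(),
                                              cell_row = integer()), g))))
})

test_that("union centroid equals the mean-of-cell-centres oracle", {
  g <- GridSpec()
  cs <- cellSize(g)
  set.seed(408)
  for (i in 1:50) {
    cells <- randomCellSet(sample(2:30, 1))
    got <- unionCentroid(cells, g)
    oracle <- inverseProject(g, mean((cells$cell_col + 0.5) * cs),
                                mean((cells$cell_row + 0.5) * cs))
    p1 <- projectPoints(g, got["lon"], got["lat"])
    p2 <- projectPoints(g, oracle$lon, oracle$lat)
    expect_lt(sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2), 1e-9)
  }
})

test_that("bounds match the corner-enumeration oracle exactly", {
  g <- GridSpec()
  one <- cellsDT(cell_col = -100L, cell_row = 250L)
  b <- boundsOf(one, g)
  corners <- inverseProject(g, c(-100, -99, -99, -100) * 1e4,
                               c(250, 250, 251, 251) * 1e4)
  expect_equal(unname(b["min_lat"]), min(corners$lat))
  expect_equal(unname(b["max_lon"]), max(corners$lon))
  # adding a cell strictly inside current bounds leaves them unchanged
  spread <- cellsDT(cell_col = c(-110L, -90L), cell_row = c(240L, 260L))
  withInner <- rbind(spread, cellsDT(cell_col = -100L, cell_row = 250L))
  expect_equal(boundsOf(withInner, g), boundsOf(spread, g))
  # 20 random sets against brute-force enumeration of all 4n corners
  set.seed(409)
  for (i in 1:20) {
    cells <- randomCellSet(sample(2:25, 1))
    b <- boundsOf(cells, g)
    cx <- as.vector(outer(cells$cell_col, c(0, 1, 1, 0), `+`)) * 1e4
    cy <- as.vector(outer(cells$cell_row, c(0, 0, 1, 1), `+`)) * 1e4
    geo <- inverseProject(g, cx, cy)
    expect_identical(unname(b),
                     c(min(geo$lat), max(geo$lat), min(geo$lon),
                       max(geo$lon)))
  }
})

test_that("centroid is translation-equivariant by one cell width", {
  g <- GridSpec()
  set.seed(410)
  cells <- randomCellSet(12)
  shifted <- data.table::copy(cells)[, cell_col := cell_col + 1L]
  p0 <- unionCentroid(cells, g)
  p1 <- unionCentroid(shifted, g)
  q0 <- projectPoints(g, p0["lon"], p0["lat"])
  q1 <- projectPoints(g, p1["lon"], p1["lat"])
  expect_equal(q1$x - q0$x, cellSize(g), tolerance = 1e-9)
  expect_equal(q1$y - q0$y, 0, tolerance = 1e-9)
})

test_that("annual summaries match hand computation on a 3-cell layout", {
  g <- GridSpec()
  # three cells in one region; detections in two of them
  pts <- inverseProject(g, c(-1005000, -995000, -985000),
                           c(2505000, 2505000, 2505000))
  ev <- makeEvents(sprintf("S%02d", 1:9),
                   lat = rep(pts$lat, each = 3), lon = rep(pts$lon, each = 3),
                   date = as.Date("2015-06-01"))
  zf <- zeroFill(ev, makeObs(c("S01", "S04")))
  a <- assignCells(zf, g)
  retained <- unique(a[, c("cell_col", "cell_row")])
  rs <- RegionSet("all", list(cbind(lon = c(-130, -80, -80, -130),
                                    lat = c(20, 20, 60, 60))))
  cym <- scoreCellYears(a, retained, g, rs)
  s <- annualSummaries(cym)
  s <- s[s$region == "all", ]
  expect_equal(s$n_det_cells, 2L)
  expect_equal(s$n_effort_cells, 3L)
  detOracle <- unionCentroid(retained[1:2], g)
  effOracle <- unionCentroid(retained, g)
  expect_equal(s$det_centroid_lat, unname(detOracle["lat"]))
  expect_equal(s$effort_centroid_lat, unname(effOracle["lat"]))
  expect_equal(
    unname(boundsOf(retained, g)),
    unname(unlist(s[, c("effort_min_lat", "effort_max_lat",
                        "effort_min_lon", "effort_max_lon")])))
})

test_that("summary fast path equals the reference operations region-by-region", {
  set.seed(411)
  sc <- SyntheticConfig(years = c(2013L, 2015L), nPerYear = 1200L, seed = 9L)
  sim <- generateChecklists(sc)
  fl <- applyFilters(zeroFill(sim$events, sim$observations),
                     FilterConfig(yearRange = c(2013L, 2015L)))
  g <- GridSpec()
  a <- assignCells(fl$kept, g)
  ret <- retainCells(cellYearCounts(a), 2)
  rs <- makeRegionFixture("two_rectangles")
  cym <- scoreCellYears(a, ret, g, rs)
  s <- annualSummaries(cym)
  rd <- SummarizedExperiment::rowData(cym)
  cells <- data.table::data.table(cell_col = rd$cellCol,
                                  cell_row = rd$cellRow)
  det <- detectionCounts(cym) >= 1
  for (k in sample(nrow(s), 5)) {
    row <- s[k]
    inReg <- if (row$region == "full_range") !is.na(rd$region)
             else !is.na(rd$region) & rd$region == row$region
    idx <- which(inReg & det[, as.character(row$year)])
    ref <- unionCentroid(cells[idx], g)
    expect_equal(row$det_centroid_lat, unname(ref["lat"]))
    expect_equal(row$det_centroid_lon, unname(ref["lon"]))
    refB <- boundsOf(cells[idx], g)
    expect_equal(row$det_min_lat, unname(refB["min_lat"]))
    expect_equal(row$det_max_lon, unname(refB["max_lon"]))
  }
})

test_that("detection metrics stay inside effort metrics", {
  set.seed(412)
  out <- runSyntheticAnalysis(SyntheticConfig(seed = 21L,
                                              nPerYear = 1500L))
  s <- out$summaries
  ok <- !is.na(s$det_min_lat)
  expect_true(all(s$det_min_lat[ok] >= s$effort_min_lat[ok]))
  expect_true(all(s$det_max_lat[ok] <= s$effort_max_lat[ok]))
  expect_true(all(s$det_min_lon[ok] >= s$effort_min_lon[ok]))
  expect_true(all(s$det_max_lon[ok] <= s$effort_max_lon[ok]))
  expect_true(all(s$n_det_cells <= s$n_effort_cells))
  # region-years with no detections carry the EMPTY encoding
  none <- s$n_det_cells == 0
  expect_true(all(is.na(s$det_centroid_lat[none])))
})
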