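test_that("projection round-trips and is equal-area against the closed form", {
  g <- GridSpec()
  set.seed(404)
  lon <- runif(200, -130, -90)
  lat <- runif(200, 30, 55)
  xy <- projectPoints(g, lon, lat)
  back <- inverseProject(g, xy$x, xy$y)
  expect_equal(back$lon, lon, tolerance = 1e-9)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  # projected area of random geographic quadrilaterals must equal the
  # spherical closed-form area (the defining property of an equal-area
  # projection)
  for (i in 1:25) {
    lo <- runif(1, -125, -100); la <- runif(1, 35, 50)
    dlo <- runif(1, 0.05, 0.5); dla <- runif(1, 0.05, 0.5)
    # densify the ring: projected edges are curved images of the
    # geographic edges, so a 4-corner shoelace would measure chords
    t <- seq(0, 1, length.out = 25)
    ringLon <- c(lo + t * dlo, rep(lo + dlo, 25), lo + rev(t) * dlo,
                 rep(lo, 25))
    ringLat <- c(rep(la, 25), la + t * dla, rep(la + dla, 25),
                 la + rev(t) * dla)
    ring <- projectPoints(g, ringLon, ringLat)
    aProj <- shoelaceArea(ring$x, ring$y)
    aSphere <- sphericalQuadArea(lo, lo + dlo, la, la + dla, gridRadius(g))
    expect_equal(aProj, aSphere, tolerance = 1e-6)
  }
  expect_error(projectPoints(g, 200, 10), "failing projection")
})

test_that("cell assignment implements the half-open floor rule", {
  g <- GridSpec()
  # construct records whose projected coordinates are known (to within the
  # geographic round trip, well under a metre)
  pts <- inverseProject(g, c(5000, 10000.5, 9999.5, 10000.5),
                           c(5000, 0, 500, 500))
  recs <- makeEvents(sprintf("S%d", 1:4), lat = pts$lat, lon = pts$lon)
  a <- assignCells(recs, g)
  expect_equal(a$cell_col, c(0, 1, 0, 1))
  expect_equal(a$cell_row, c(0, 0, 0, 0))
  # two points one metre apart straddling a boundary land in different cells
  expect_false(a$cell_col[3] == a$cell_col[4])
})

test_that("cell retention requires the minimum number of sampled years", {
  mkSumm <- function(years) data.table::data.table(
    cell_col = 1L, cell_row = 1L, year = years, n_checklists = 1L,
    n_detections = 0L)
  expect_equal(nrow(retainCells(mkSumm(c(2010, 2012, 2014, 2016)), 5)), 0L)
  expect_equal(nrow(retainCells(mkSumm(c(2010, 2012, 2014, 2016, 2018)), 5)),
               1L)
  expect_equal(nrow(retainCells(mkSumm(2015), 1)), 1L)
  # monotone: lowering the threshold never removes a retained cell
  set.seed(405)
  summ <- data.table::data.table(
    cell_col = sample(1:30, 400, TRUE), cell_row = sample(1:30, 400, TRUE),
    year = sample(2010:2022, 400, TRUE), n_checklists = 1L,
    n_detections = 0L)
  prev <- NULL
  for (m in c(7, 5, 3, 1)) {
    cur <- retainCells(summ, m)
    if (!is.null(prev))
      expect_true(nrow(data.table::fsetdiff(prev, cur)) == 0L)
    prev <- cur
  }
})

test_that("cell-year scoring counts checklists and detections per retained cell", {
  g <- GridSpec()
  pt <- inverseProject(g, 15000, 15000)   # cell (1,1)
  pt2 <- inverseProject(g, 25000, 15000)  # cell (2,1)
  ev <- makeEvents(sprintf("S%02d", 1:7), lat = c(rep(pt$lat, 4), rep(pt2$lat, 3)),
                   lon = c(rep(pt$lon, 4), rep(pt2$lon, 3)))
  zf <- zeroFill(ev, makeObs("S01"))
  a <- assignCells(zf, g)
  # retain only cell (1,1)
  retained <- data.table::data.table(cell_col = 1, cell_row = 1)
  rs <- RegionSet("all", list(cbind(lon = c(-130, -80, -80, -130),
                                    lat = c(20, 20, 60, 60))))
  cym <- scoreCellYears(a, retained, g, rs)
  expect_s4_class(cym, "CellYearMatrix")
  expect_equal(nrow(cym), 1L)  # dropped cell emits nothing
  expect_equal(as.vector(checklistCounts(cym)), 4L)
  expect_equal(as.vector(detectionCounts(cym)), 1L)
  expect_true(all(detectedIn(cym)))
  expect_equal(S4Vectors::metadata(cym)$grid, g)
})

test_that("CellYearMatrix validity rejects impossible counts", {
  g <- GridSpec()
  rd <- S4Vectors::DataFrame(cellCol = 1L, cellRow = 1L, centerX = 15000,
                             centerY = 15000, centerLon = -96, centerLat = 30)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(checklists = matrix(1L), detections = matrix(2L)),
    rowData = rd, metadata = list(grid = g))
  expect_error(methods::new("CellYearMatrix", se), "exceed")
})

test_that("region assignment matches a ray-casting oracle and breaks ties by order", {
  rs <- makeRegionFixture("two_rectangles")
  polys <- regionPolygons(rs)
  set.seed(406)
  lon <- runif(100, -120, -100)
  lat <- runif(100, 38, 51)
  got <- assignRegion(lon, lat, rs)
  inW <- rayCastOracle(polys$west, lon, lat)
  inE <- rayCastOracle(polys$east, lon, lat)
  oracle <- ifelse(inW, "west", ifelse(inE, "east", NA_character_))
  expect_equal(got, oracle)
  # interior / exterior sanity
  expect_equal(assignRegion(-113, 45, rs), "west")
  expect_true(is.na(assignRegion(-90, 45, rs)))
})

test_that("every record maps to one cell and at most one region", {
  set.seed(407)
  sim <- generateChecklists(SyntheticConfig(years = c(2016L, 2016L),
                                            nPerYear = 500L, seed = 5L))
  recs <- assignCells(zeroFill(sim$events, sim$observations))
  expect_false(anyNA(recs$cell_col))
  expect_false(anyNA(recs$cell_row))
  rs <- makeRegionFixture("eight_band")
  reg <- assignRegion(recs$lon, recs$lat, rs)
  expect_true(all(is.na(reg) | reg %in% regionNames(rs)))
})
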