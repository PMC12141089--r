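# shared fixtures and independent oracles, built in code at test time

# minimal sampling-event table; all effort values pass the default filters
makeEvents <- function(ids, lat = 44, lon = -110, protocol = "stationary",
                       date = as.Date("2015-06-15"), duration = 60,
                       distance = NA_real_, complete = TRUE,
                       group = NA_character_) {
  n <- length(ids)
  data.table::data.table(
    checklist_id = ids,
    group_id = rep_len(group, n),
    protocol = rep_len(protocol, n),
    date = rep_len(date, n),
    duration_minutes = rep_len(duration, n),
    distance_km = rep_len(distance, n),
    n_observers = 1L,
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    complete = rep_len(complete, n))
}

makeObs <- function(ids, count = 1L) {
  data.table::data.table(checklist_id = ids, species_code = "lobcur",
                         count = rep_len(as.integer(count), length(ids)))
}

# checklist records directly (zero-filled form)
makeRecords <- function(n, detectedIdx = integer(), ...) {
  ev <- makeEvents(sprintf("S%04d", seq_len(n)), ...)
  ob <- makeObs(ev$checklist_id[detectedIdx])
  gridShift::zeroFill(ev, ob)
}

# independent ray-casting point-in-polygon oracle (even-odd rule)
rayCastOracle <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# random distinct grid-cell sets over a plausible window of the default grid
randomCellSet <- function(nCells, colRange = c(-170, -55),
                          rowRange = c(205, 300)) {
  cells <- unique(data.table::data.table(
    cell_col = sample(seq(colRange[1], colRange[2]), nCells, replace = TRUE),
    cell_row = sample(seq(rowRange[1], rowRange[2]), nCells, replace = TRUE)))
  cells
}

# area of the spherical quadrilateral [lon1,lon2] x [lat1,lat2] on the
# sphere of radius R (closed form; independent check of equal-area claims)
sphericalQuadArea <- function(lon1, lon2, lat1, lat2, R) {
  R^2 * abs(lon2 - lon1) * pi / 180 *
    abs(sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

# shoelace area of a closed polygon given projected vertices
shoelaceArea <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
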