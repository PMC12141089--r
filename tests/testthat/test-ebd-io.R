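test_that("observation reader parses counts, filters species, honours 'X'", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SAMPLING EVENT IDENTIFIER\tSPECIES CODE\tOBSERVATION COUNT",
    "S1\tlobcur\t2", "S2\tlobcur\tX", "S3\tlobcur\t1", "S4\tkilldee\t7"),
    f)
  obs <- readObservations(f, "lobcur")
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$count, c(2L, NA_integer_, 1L))
  expect_equal(nrow(readObservations(f, "lobshr")), 0L)
})

test_that("observation reader errors name the missing column and bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SAMPLING EVENT IDENTIFIER\tSPECIES CODE",
               "S1\tlobcur"), f)
  expect_error(readObservations(f, "lobcur"), "OBSERVATION COUNT")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SAMPLING EVENT IDENTIFIER\tSPECIES CODE\tOBSERVATION COUNT",
               "S1\tlobcur\t2", "S2\tlobcur\tmany"), f2)
  expect_error(readObservations(f2, "lobcur"), "row")
})

test_that("zero-filling conserves events and flags detections", {
  ev <- makeEvents(sprintf("S%02d", 1:10))
  ob <- makeObs(c("S02", "S05", "S09"), count = c(3L, 1L, 2L))
  zf <- zeroFill(ev, ob)
  expect_equal(nrow(zf), 10L)
  expect_equal(sum(zf$detected), 3L)
  expect_true(all(zf$count[!zf$detected] == 0L))
  expect_equal(zf$count[zf$checklist_id == "S02"], 3L)
  # empty case
  empty <- zeroFill(makeEvents(character()), makeObs(character()))
  expect_equal(nrow(empty), 0L)
})

test_that("orphan observations are rejected by id", {
  ev <- makeEvents(sprintf("S%02d", 1:5))
  ob <- makeObs(c("S01", "Z9"))
  expect_error(zeroFill(ev, ob), "Z9")
})

test_that("zero-fill conservation and idempotence hold on random inputs", {
  set.seed(401)
  for (i in 1:20) {
    n <- sample(1:200, 1)
    ev <- makeEvents(sprintf("E%04d", seq_len(n)))
    det <- sample(n, sample(0:n, 1))
    ob <- makeObs(ev$checklist_id[det])
    zf <- zeroFill(ev, ob)
    expect_equal(nrow(zf), n)
    expect_equal(sum(zf$detected), length(det))
    # re-running with the same observations changes nothing
    zf2 <- zeroFill(ev, ob)
    expect_identical(zf$detected, zf2$detected)
  }
})

test_that("shared checklists collapse to one representative with OR detection", {
  r <- makeRecords(2, detectedIdx = 1, group = "G1")
  cl <- collapseShared(r)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$detected)
  expect_equal(cl$checklist_id, "S0001")
  # all-missing group ids: identity
  r2 <- makeRecords(4, detectedIdx = 2)
  expect_equal(collapseShared(r2), r2)
})

test_that("collapse matches a grouping-count oracle", {
  # three records in two groups plus one ungrouped -> 3 records
  r <- makeRecords(4, detectedIdx = c(1, 4),
                   group = c("GA", "GA", "GB", NA))
  cl <- collapseShared(r)
  oracleN <- length(unique(stats::na.omit(r$group_id))) +
    sum(is.na(r$group_id))
  expect_equal(nrow(cl), oracleN)
  expect_equal(nrow(cl), 3L)
  # collapsing never increases the number of detected records
  set.seed(77)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    r <- makeRecords(n, detectedIdx = sample(n, sample(0:n, 1)),
                     group = sample(c(NA, "g1", "g2", "g3"), n,
                                    replace = TRUE))
    expect_lte(sum(collapseShared(r)$detected), sum(r$detected))
  }
})

test_that("EBD dialect round-trips through the writers and readers", {
  ev <- makeEvents(sprintf("S%02d", 1:6),
                   protocol = c("stationary", "traveling"),
                   distance = c(NA, 2.5), group = c(NA, NA, "G7", NA, NA, NA))
  ob <- makeObs(c("S01", "S04"), count = c(2L, NA))  # NA = "X"
  fe <- withr::local_tempfile(fileext = ".tsv")
  fo <- withr::local_tempfile(fileext = ".tsv")
  writeSamplingEvents(ev, fe)
  writeObservations(ob, fo)
  ev2 <- readSamplingEvents(fe)
  ob2 <- readObservations(fo, "lobcur")
  expect_equal(ev2$checklist_id, ev$checklist_id)
  expect_equal(ev2$protocol, ev$protocol)
  expect_equal(ev2$distance_km, ev$distance_km)
  expect_equal(ev2$group_id, ev$group_id)
  expect_equal(ob2$count, ob$count)
  # zero-filled table round trip
  zf <- zeroFill(ev, ob)
  fc <- withr::local_tempfile(fileext = ".tsv")
  writeChecklists(zf, fc)
  zf2 <- readChecklists(fc)
  expect_equal(zf2$detected, zf$detected)
  expect_equal(zf2$count, zf$count)
  expect_equal(zf2$lat, zf$lat, tolerance = 1e-6)
})
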