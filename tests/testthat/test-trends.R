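test_that("an exact linear signal is recovered perfectly", {
  years <- 2010:2022
  cov <- c(1, 3, 2, 5, 4, 6, 5, 8, 7, 9, 8, 11, 10) / 10
  resp <- 2 * years + 0 * cov
  ft <- suppressWarnings(fitTrend(years, resp, cov))
  expect_equal(ft$slope, 2, tolerance = 1e-8)
  expect_lt(ft$p, 1e-10)
  expect_equal(ft$adj_r2, 1, tolerance = 1e-8)
  expect_equal(ft$status, "OK")
  # constant response: zero slope and zero cumulative km
  ft0 <- suppressWarnings(fitTrend(years, rep(45.2, 13), cov))
  expect_equal(ft0$slope, 0, tolerance = 1e-12)
  expect_equal(toCumulativeKm(ft0$slope, "centroid_lat"), 0)
})

test_that("slope estimation is unbiased under the generative model", {
  # response = 0.1*year + 0.5*covariate + N(0, 0.01), 13 years
  set.seed(413)
  years <- 2010:2022
  slopes <- replicate(1000, {
    cov <- rnorm(13, 0, 0.3)
    resp <- 0.1 * years + 0.5 * cov + rnorm(13, 0, 0.01)
    fitTrend(years, resp, cov)$slope
  })
  expect_lt(abs(mean(slopes) - 0.1), 0.005)
})

test_that("degenerate fits are reported, not crashed", {
  years <- 2010:2022
  short <- fitTrend(years[1:3], c(1, 2, 3), c(1, 2, 4))
  expect_equal(short$status, "INSUFFICIENT")
  expect_true(is.na(short$slope))
  # missing values are dropped pairwise before the n >= 4 check
  resp <- c(1:5, rep(NA, 8))
  miss <- fitTrend(years, resp, rnorm(13))
  expect_equal(miss$n_years, 5L)
  expect_equal(miss$status, "OK")
  expect_error(fitTrend(years, rnorm(13), 2 * years + 3), "collinear")
})

test_that("variance inflation factor agrees with the standard diagnostic", {
  set.seed(414)
  years <- 2010:2022
  cov <- 0.05 * years + rnorm(13, 0, 0.2)
  resp <- rnorm(13, 45, 0.5)
  ft <- fitTrend(years, resp, cov)
  fit <- lm(resp ~ years + cov)
  expect_equal(unname(ft$vif), unname(car::vif(fit)["years"]),
               tolerance = 1e-10)
})

test_that("degree-to-kilometre conversion behaves geometrically", {
  conv <- KmConversion()
  # zero slope maps to zero km; sign is preserved and the map is linear
  expect_equal(toCumulativeKm(0, "limit_N", conv), 0)
  s <- 0.07
  expect_equal(toCumulativeKm(-s, "centroid_lat", conv),
               -toCumulativeKm(s, "centroid_lat", conv))
  expect_equal(toCumulativeKm(3 * s, "centroid_lat", conv),
               3 * toCumulativeKm(s, "centroid_lat", conv))
  # meridian convergence: at 60 N a longitude degree is half an equator one
  at0 <- toCumulativeKm(s, "centroid_lon", conv, referenceLat = 0)
  at60 <- toCumulativeKm(s, "centroid_lon", conv, referenceLat = 60)
  expect_equal(at60, at0 / 2, tolerance = 1e-12)
  expect_equal(toCumulativeKm(s, "centroid_lon", conv, referenceLat = 60,
                              applyCos = FALSE), at0)
  expect_error(toCumulativeKm(s, "centroid_lon", conv, referenceLat = 90),
               "reference latitude")
  expect_error(KmConversion(spanYears = 1), "spanYears")
})

test_that("the trend battery covers 4 limits + 2 axes range-wide and 2 axes per region", {
  set.seed(415)
  out <- runSyntheticAnalysis(SyntheticConfig(seed = 31L, nPerYear = 2000L))
  tr <- out$trends
  expect_equal(nrow(tr), 8L * 2L + 6L)
  expect_setequal(tr$metric[tr$region == "full_range"],
                  c("centroid_lat", "centroid_lon", "limit_N", "limit_S",
                    "limit_E", "limit_W"))
  expect_true(all(tr$metric[tr$region != "full_range"] %in%
                  c("centroid_lat", "centroid_lon")))
  okRows <- tr$status == "OK"
  expect_true(all(tr$p[okRows] >= 0 & tr$p[okRows] <= 1))
  expect_true(all(tr$vif[okRows] >= 1))
  # direction labels are sign-consistent with slopes
  lat <- okRows & tr$metric %in% c("centroid_lat", "limit_N", "limit_S")
  expect_true(all(tr$direction[lat & tr$slope > 0] == "N"))
  expect_true(all(tr$direction[lat & tr$slope < 0] == "S"))
  lon <- okRows & !lat
  expect_true(all(tr$direction[lon & tr$slope > 0] == "E"))
  expect_true(all(tr$direction[lon & tr$slope < 0] == "W"))
  # cumulative km is consistent with its own slope and span
  conv <- KmConversion()
  latRows <- which(lat)
  expect_equal(tr$cumulative_km[latRows],
               tr$slope[latRows] * 13 * 111.32, tolerance = 1e-9)
})
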