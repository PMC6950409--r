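test_that("circular kernel matches brute-force membership and symmetry", {
  k <- circular_kernel(50, 50)
  expect_equal(nrow(k), 5)
  expect_setequal(paste(k[, 1], k[, 2]),
                  c("0 0", "1 0", "-1 0", "0 1", "0 -1"))

  tiny <- circular_kernel(10, 50)   # radius < cell/sqrt(2)
  expect_equal(unname(tiny), matrix(0L, 1, 2))

  big <- circular_kernel(5000, 50)
  m <- 100
  brute <- sum(outer((-m:m)^2, (-m:m)^2, `+`) * 50^2 <= 5000^2)
  expect_equal(nrow(big), brute)

  # symmetric under 90-degree rotation and reflection
  key <- function(a, b) paste(a, b)
  expect_setequal(key(k[, 1], k[, 2]), key(-k[, 2], k[, 1]))
  expect_setequal(key(big[, 1], big[, 2]), key(big[, 2], big[, 1]))
  expect_setequal(key(big[, 1], big[, 2]), key(-big[, 1], big[, 2]))
})

test_that("focal statistics agree exactly with the nested-loop brute force", {
  g <- grid_spec(0, 0, 50, 12, 15)
  set.seed(5)
  r <- feature_raster(g, matrix(runif(12 * 15), 12, 15), name = "z")
  for (radius in c(50, 120, 300)) {
    for (stat in c("sum", "mean")) {
      got <- focal_stat(r, radius, stat)$values
      want <- oracle_focal_cell(r$values, radius, 50, stat)
      expect_equal(got, want, tolerance = 0)
    }
  }
})

test_that("focal edge cases: constants, the 3x3 mask, missing neighborhoods", {
  g <- grid_spec(0, 0, 50, 9, 9)
  const <- feature_raster(g, matrix(4.2, 9, 9))
  expect_equal(focal_stat(const, 333, "mean")$values, matrix(4.2, 9, 9))

  g3 <- grid_spec(0, 0, 50, 3, 3)
  ones <- feature_raster(g3, matrix(1, 3, 3))
  expect_equal(focal_stat(ones, 50, "sum")$values[2, 2], 5)

  withNA <- matrix(runif(81), 9, 9)
  withNA[1:3, 1:3] <- NA
  got <- focal_stat(feature_raster(g, withNA), 50, "mean")$values
  expect_true(is.na(got[1, 1]))         # all kernel members missing
  expect_false(anyNA(got[5:9, 5:9]))
  expect_equal(got, oracle_focal_cell(withNA, 50, 50, "mean"), tolerance = 0)
})

test_that("focal sum is radius-monotone and translation-equivariant", {
  g <- grid_spec(0, 0, 50, 20, 20)
  ones <- feature_raster(g, matrix(1, 20, 20))
  prev <- NULL
  for (radius in c(100, 200, 300, 500)) {
    cur <- focal_stat(ones, radius, "sum")$values
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }

  set.seed(8)
  vals <- matrix(rnorm(400), 20, 20)
  shifted <- matrix(0, 20, 20)
  shifted[4:20, ] <- vals[1:17, ]      # shift down by 3 rows
  a <- focal_stat(feature_raster(g, vals), 150, "sum")$values
  b <- focal_stat(feature_raster(g, shifted), 150, "sum")$values
  # interior of the shifted output equals the shifted interior (rows whose
  # kernel stays off the pad)
  expect_equal(b[7:17, 4:17], a[4:14, 4:17])
})

test_that("point-wise focal equals full-surface focal at the query cells", {
  g <- grid_spec(0, 0, 50, 25, 25)
  set.seed(3)
  r <- feature_raster(g, matrix(runif(625), 25, 25))
  pts <- data.frame(x = runif(15, 0, 25 * 50), y = runif(15, 0, 25 * 50))
  for (radius in c(75, 400)) {
    full <- focal_stat(r, radius, "mean")
    expect_identical(focal_at_points(r, pts, radius, "mean"),
                     extract_at(full, pts))
  }
})

test_that("nearest distance handles points, segments and random oracles", {
  pts <- vector_features(layer = "P",
                         wkt = c("POINT (0 0)", "POINT (100 0)"))
  expect_equal(nearest_distance(pts, data.frame(x = 0, y = 0)), 0)
  expect_equal(nearest_distance(pts, data.frame(x = 30, y = 40)), 50)

  seg <- vector_features("L", "LINESTRING (0 0, 100 0, 100 100)")
  expect_equal(nearest_distance(seg, data.frame(x = 50, y = 30)), 30)
  expect_equal(nearest_distance(seg, data.frame(x = 130, y = 50)), 30)
  expect_equal(nearest_distance(seg, data.frame(x = -30, y = -40)), 50)

  set.seed(12)
  feat <- vector_features("P", sprintf("POINT (%f %f)", runif(50, 0, 1000),
                                       runif(50, 0, 1000)))
  q <- data.frame(x = runif(20, 0, 1000), y = runif(20, 0, 1000))
  fx <- t(vapply(feat$wkt, function(w) lurkit:::parse_wkt(w)$coords[1, ],
                 numeric(2)))
  brute <- vapply(seq_len(20), function(i) {
    min(sqrt((fx[, 1] - q$x[i])^2 + (fx[, 2] - q$y[i])^2))
  }, numeric(1))
  expect_equal(nearest_distance(feat, q), brute)

  expect_error(nearest_distance(feat[0, ], q), "empty")
})

test_that("extraction follows the half-open cell convention", {
  g <- grid_spec(0, 0, 50, 4, 4)
  vals <- matrix(seq_len(16), 4, 4)
  r <- feature_raster(g, vals)
  expect_equal(extract_at(r, data.frame(x = 75, y = 125)), vals[3, 2])
  # a point exactly on the shared edge belongs to the east/north cell
  expect_equal(extract_at(r, data.frame(x = 50, y = 50)), vals[2, 2])
  expect_equal(extract_at(r, data.frame(x = 0, y = 0)), vals[1, 1])

  set.seed(4)
  q <- data.frame(x = runif(10, 0, 199.99), y = runif(10, 0, 199.99))
  expect_equal(extract_at(r, q),
               vals[cbind(floor(q$y / 50) + 1, floor(q$x / 50) + 1)])

  bad <- data.frame(x = 500, y = 10, station_id = "pm99")
  expect_error(extract_at(r, bad, id = "station_id"), "pm99")
})

test_that("feature stack enumerates classes x radii plus NDVI and distances", {
  g <- grid_spec(0, 0, 50, 30, 30)
  lu <- generate_landuse(21, g, c(Residential = 0.4, Industrial = 0.1))
  ndvi <- generate_ndvi(22, g, "2016-01")$composites[["2016-01"]]
  vec <- vector_features("Airport", "POINT (750 750)")
  ladder <- buffer_ladder(c(250, 500, 1000, 1500))
  stack <- build_feature_stack(lu, ndvi, vec, ladder)
  expect_length(stack, 2 * 4 + 4 + 1)
  expect_true("Residential_1000m" %in% names(stack))
  expect_true("NDVI_250m" %in% names(stack))
  expect_true("Airport_nearest" %in% names(stack))

  parsed <- parse_feature_name(names(stack))
  expect_equal(sum(parsed$layer == "Residential"), 4)
  expect_equal(parsed$radius[parsed$name == "NDVI_1500m"], 1500)
  expect_true(all(vapply(stack, function(r) all(is.finite(r$values)),
                         logical(1))))
  # class-area units: full coverage within the buffer = disc area in ha
  all_res <- generate_landuse(1, g, c(Residential = 1))
  disc <- build_feature_stack(all_res, NULL, NULL, buffer_ladder(250))
  k <- nrow(circular_kernel(250, 50))
  expect_equal(disc$Residential_250m$values[15, 15], k * 0.25)
})
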