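test_that("CV folds partition the rows with near-equal sizes", {
  set.seed(81)
  x <- rnorm(103)
  d <- make_design(data.frame(x = x), pm25 = 5 + 2 * x + rnorm(103, 0, 0.3))
  m <- supervised_stepwise(d)
  cv <- kfold_cv(d, m, k = 10, seed = 4)
  expect_length(cv$folds, 103)
  expect_setequal(unique(cv$folds), 1:10)
  sizes <- table(cv$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  # training share = (k-1)/k of rows within one observation
  expect_true(all(abs((103 - sizes) - 0.9 * 103) <= 1))
  # seeded assignment is reproducible
  expect_identical(cv$folds, kfold_cv(d, m, k = 10, seed = 4)$folds)
  expect_false(identical(cv$folds, kfold_cv(d, m, k = 10, seed = 5)$folds))
})

test_that("noiseless responses cross-validate perfectly", {
  x <- seq(0, 10, length.out = 60)
  d <- make_design(data.frame(x = x), pm25 = 4 + 3 * x)
  m <- supervised_stepwise(d)
  cv <- kfold_cv(d, m, k = 10, seed = 1)
  expect_equal(cv$r2, 1, tolerance = 1e-12)
  expect_lt(cv$rmse, 1e-9)
})

test_that("leave-one-out degenerate case predicts each row exactly once", {
  set.seed(91)
  x <- rnorm(24)
  d <- make_design(data.frame(x = x), pm25 = 1 + x + rnorm(24, 0, 0.2))
  m <- supervised_stepwise(d)
  cv <- kfold_cv(d, m, k = 12, seed = 2)
  expect_equal(as.integer(table(cv$folds)), rep(2L, 12))
  expect_false(anyNA(cv$predictions$predicted))
  expect_equal(nrow(cv$predictions), 24)
})

test_that("out-of-fold R^2 tracks in-sample R^2 for a well-specified model", {
  s <- simulate_lur_dataset(303)
  m <- supervised_stepwise(s$design)
  cv <- kfold_cv(s$design, m, k = 10, seed = 3)
  expect_lt(abs(cv$r2 - m$r2), 0.1)
  expect_error(kfold_cv(s$design, m, k = 300, seed = 1), "2k")
})

test_that("re-selection inside folds is supported", {
  set.seed(95)
  x1 <- rnorm(80); x2 <- rnorm(80)
  d <- make_design(data.frame(x1 = x1, x2 = x2),
                   pm25 = 2 + 3 * x1 + rnorm(80, 0, 0.4))
  cv <- kfold_cv(d, k = 5, seed = 9, refit_selection = TRUE)
  expect_gt(cv$r2, 0.9)
})

test_that("prediction surfaces evaluate the regression equation cellwise", {
  g <- grid_spec(0, 0, 50, 15, 15)
  # intercept-only model: constant surface
  d0 <- make_design(data.frame(z = rnorm(30)), pm25 = rnorm(30, 12, 0.01))
  m0 <- suppressWarnings(supervised_stepwise(
    make_design(data.frame(z = rep(0, 30) + c(rep(0, 29), 1e-9)),
                pm25 = rep(12, 30))))
  r <- feature_raster(g, matrix(rnorm(225), 15, 15), name = "z")
  expect_true(all(abs(predict_surface(m0, list(z = r))$values - 12) < 1e-6))

  # one-term model: hand dot product at random cells
  set.seed(14)
  x <- rnorm(60)
  d1 <- make_design(data.frame(z = x), pm25 = 5 + 2 * x)
  m1 <- supervised_stepwise(d1)
  surf <- predict_surface(m1, list(z = r))
  idx <- cbind(sample(15, 5, replace = TRUE), sample(15, 5, replace = TRUE))
  expect_equal(surf$values[idx],
               m1$intercept + m1$terms$beta[1] * r$values[idx],
               tolerance = 1e-12)

  expect_error(predict_surface(m1, list(other = r)), "z")

  # flooring is optional and logged
  neg <- feature_raster(g, matrix(-10, 15, 15), name = "z")
  floored <- predict_surface(m1, list(z = neg), floor_at_zero = TRUE)
  expect_true(all(floored$values >= 0))
  expect_equal(attr(floored, "n_floored"), 225)
})

test_that("monitor-cell surface predictions equal tabular predictions", {
  s <- simulate_lur_study(404, grid = grid_spec(0, 0, 50, 40, 40),
                          n_stations = 6, n_months = 4, n_meteo_stations = 3,
                          ladder = c(250, 500, 1000), target_r2 = NULL,
                          truth = ground_truth(10, c(Residential_500m = 0.05,
                                                     NDVI_1000m = -40), 2))
  # static-predictor model: land-use terms only
  d <- s$design
  keep <- d$candidates$name[d$candidates$var_class %in%
                              c("land_use", "distance")]
  fit <- supervised_stepwise(structure(list(
    data = d$data, candidates = d$candidates[d$candidates$name %in% keep, ],
    response = "pm25"), class = "lur_design"))
  if (nrow(fit$terms) > 0) {
    stack <- build_feature_stack(s$landuse, NULL, s$landuse$vectors,
                                 buffer_ladder(c(250, 500, 1000)))
    surf <- predict_surface(fit, stack)
    at_monitors <- extract_at(surf, s$stations)
    tab <- fit$intercept +
      as.matrix(d$data[match(s$stations$station_id, d$data$station_id),
                       fit$terms$name, drop = FALSE]) %*% fit$terms$beta
    expect_equal(at_monitors, as.vector(tab), tolerance = 1e-9)
  } else {
    succeed("selection returned an intercept-only static model")
  }
})

test_that("period averaging and exceedance counting are cellwise exact", {
  g <- grid_spec(0, 0, 50, 8, 8)
  r10 <- feature_raster(g, matrix(10, 8, 8))
  r20 <- feature_raster(g, matrix(20, 8, 8))
  avg <- period_average(list(r10, r20), period = "2016")
  expect_true(all(avg$values == 15))
  expect_identical(period_average(list(r10, r10, r10))$values, r10$values)

  # pooled mean equals mean of complete yearly means
  set.seed(15)
  months <- lapply(1:24, function(i) feature_raster(g, matrix(rnorm(64), 8, 8)))
  y1 <- period_average(months[1:12]); y2 <- period_average(months[13:24])
  pooled <- period_average(months)
  expect_equal(pooled$values, (y1$values + y2$values) / 2, tolerance = 1e-12)
  expect_error(period_average(list()), "no rasters")

  const12 <- feature_raster(g, matrix(12, 8, 8))
  ex <- exceedance_summary(const12)
  expect_equal(ex$fraction[ex$threshold_name == "WHO_annual"], 1)
  expect_equal(ex$fraction[ex$threshold_name == "Indonesia_annual"], 0)

  mixed <- feature_raster(g, matrix(seq(0, 63), 8, 8))
  exm <- exceedance_summary(mixed, c(lim = 30))
  expect_equal(exm$n_exceed, sum(seq(0, 63) > 30))
  expect_equal(exm$n_cells, 64)
})

test_that("rasters round-trip through CSV with geometry preserved", {
  g <- grid_spec(500, -200, 50, 7, 9)
  r <- feature_raster(g, matrix(rnorm(63), 7, 9), name = "NDVI_1500m",
                      units = "index")
  path <- file.path(tempdir(), "r.csv")
  write_raster(r, path)
  back <- read_raster(path)
  expect_equal(back$values, r$values)
  expect_equal(back$grid, r$grid)
  expect_equal(back$name, r$name)
  unlink(c(path, paste0(path, ".json")))
})

test_that("selection traces serialise to JSON lines", {
  set.seed(16)
  x <- rnorm(40)
  d <- make_design(data.frame(x = x), pm25 = 1 + x + rnorm(40, 0, 0.3))
  m <- supervised_stepwise(d)
  path <- file.path(tempdir(), "trace.jsonl")
  write_trace(m, path)
  lines <- readLines(path)
  expect_length(lines, nrow(m$trace))
  parsed <- jsonlite::fromJSON(lines[length(lines)])
  expect_true(all(c("step", "action", "variable") %in% names(parsed)))
  unlink(path)
})
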