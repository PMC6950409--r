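# End-to-end synthetic study: scene generation -> buffer features at the
# monitors -> meteorology interpolation -> design assembly -> PM2.5 draws
# from a known ground truth. This is the single entry point the analysis
# scripts, the multi-seed experiments and the acceptance checks share.

month_seq <- function(start = "2016-01", n_months = 36) {
  first <- as.Date(paste0(start, "-01"))
  months <- seq(first, by = "month", length.out = n_months)
  data.frame(year = as.integer(format(months, "%Y")),
             month = as.integer(format(months, "%m")))
}

# buffer features (sum as hectares for class masks, mean for NDVI) at
# point coordinates, with kernels built once per radius
station_buffer_features <- function(landuse, ndvi_monthly, coords, ladder) {
  grid <- landuse$raster$grid
  idx <- cell_index(grid, coords$x, coords$y)
  kernels <- lapply(ladder, circular_kernel, cell_size = grid$cell_size)
  area_ha <- cell_area_ha(grid)
  static <- data.frame(station_id = coords$station_id)
  for (cls in names(landuse$classes)) {
    mask <- (landuse$raster$values == landuse$classes[[cls]]) * 1
    for (r in seq_along(ladder)) {
      nm <- sprintf("%s_%gm", cls, ladder[r])
      static[[nm]] <- focal_points_cpp(mask, kernels[[r]], idx$i, idx$j, 0L) *
        area_ha
    }
  }
  monthly <- NULL
  if (!is.null(ndvi_monthly)) {
    rows <- lapply(names(ndvi_monthly), function(key) {
      ym <- as.integer(strsplit(key, "-")[[1]])
      d <- data.frame(station_id = coords$station_id,
                      year = ym[1], month = ym[2])
      for (r in seq_along(ladder)) {
        d[[sprintf("NDVI_%gm", ladder[r])]] <-
          focal_points_cpp(ndvi_monthly[[key]]$values, kernels[[r]],
                           idx$i, idx$j, 1L)
      }
      d
    })
    monthly <- do.call(rbind, rows)
  }
  list(static = static, monthly = monthly)
}

# monthly meteorology interpolated from the synthetic network to the
# monitors by IDW (aggregate daily to monthly first, then interpolate)
monitor_meteo_monthly <- function(meteo, coords, periods,
                                  vars = c("Temperature", "RelativeHumidity",
                                           "WindSpeed", "Rainfall"),
                                  cfg = idw_config(),
                                  min_completeness = 0.75) {
  out <- merge(data.frame(station_id = coords$station_id), periods, by = NULL)
  for (v in vars) {
    raw_name <- meteo_var_names[[v]]
    sub <- meteo[meteo$variable == raw_name, , drop = FALSE]
    agg <- do.call(rbind, lapply(split(sub, sub$station_id), function(s) {
      m <- monthly_mean(s$date, s$value, min_completeness)
      m$x <- s$x[1]; m$y <- s$y[1]
      m
    }))
    vals <- numeric(nrow(out))
    for (r in seq_len(nrow(periods))) {
      st <- agg[agg$year == periods$year[r] & agg$month == periods$month[r], ]
      sel <- out$year == periods$year[r] & out$month == periods$month[r]
      vals[sel] <- idw(st, coords[match(out$station_id[sel],
                                        coords$station_id), ], cfg)
    }
    out[[v]] <- vals
  }
  out
}

# synthetic co-pollutant series at the monitors (co-pollutant study mode):
# station level + seasonal cycle + noise, loosely matching urban-network
# magnitudes (PM10 ~ tens, NO2 ~ 15-25 ppb, SO2 ~ 2-4 ppb)
generate_copollutants <- function(seed, coords, periods) {
  spec <- list(PM10 = c(base = 34, st = 5, amp = 6, noise = 4),
               NO2 = c(base = 19, st = 2.5, amp = 2.5, noise = 2),
               SO2 = c(base = 2.8, st = 0.3, amp = 0.3, noise = 0.25),
               UV = c(base = 6, st = 0.5, amp = 2, noise = 1))
  with_seed(seed, {
    out <- merge(data.frame(station_id = coords$station_id), periods, by = NULL)
    for (v in names(spec)) {
      p <- spec[[v]]
      lev <- setNames(rnorm(nrow(coords), 0, p[["st"]]), coords$station_id)
      season <- p[["amp"]] * cos(2 * pi * (out$month - 3) / 12)
      out[[v]] <- pmax(0, p[["base"]] + lev[out$station_id] + season +
                         rnorm(nrow(out), 0, p[["noise"]]))
    }
    out
  })
}

#' Default ground-truth model of the synthetic study
#'
#' A four-term truth mirroring the structure of a tropical-megacity
#' PM2.5 model: higher temperature and more residential area increase
#' concentrations, greenness and humidity decrease them. `noise_sd = NA`
#' marks it to be calibrated for a target true R-squared when the study
#' is simulated.
#'
#' @param seed Seed for the noise draw.
#' @return A [ground_truth()].
#' @export
default_truth <- function(seed = 1L) {
  ground_truth(intercept = -75,
               coefficients = c(Temperature = 5.8, RelativeHumidity = -0.78,
                                NDVI_1500m = -77, Residential_1000m = 0.05),
               noise_sd = 0, seed = seed)
}

#' Simulate a complete synthetic LUR study
#'
#' Generates a land-use scene, an NDVI stack, daily station meteorology
#' and monitor locations; derives the full candidate-predictor set
#' (land-use class areas and NDVI means over the buffer ladder, nearest
#' distances to airport and major-road features, interpolated monthly
#' meteorology, season indicators, optionally co-pollutants); and draws
#' monitor PM2.5 from a known ground-truth linear model. Identical
#' seeds and parameters give bit-identical studies.
#'
#' @param seed Integer master seed (sub-generators use small fixed
#'   offsets from it).
#' @param grid A [grid_spec()]; default 200 x 200 cells of 50 m (10 x
#'   10 km).
#' @param n_stations Number of PM2.5 monitors (default 17).
#' @param start First month `"YYYY-MM"`; `n_months` consecutive months.
#' @param n_months Number of monthly periods (default 36: 2016-2018).
#' @param classes Land-use classes with target fractions.
#' @param ladder Buffer radii (m) used for the candidate predictors.
#' @param truth A [ground_truth()] or `NULL` for [default_truth()]. If
#'   its `noise_sd` is 0 or `NA` and `target_r2` is set, the noise is
#'   calibrated so the true-model population R-squared equals
#'   `target_r2`.
#' @param target_r2 Target true R-squared (default 0.8); `NULL` to use
#'   the truth's own `noise_sd`.
#' @param n_meteo_stations Synthetic meteorology network size.
#' @param copollutants Include synthetic PM10/NO2/SO2/UV columns
#'   (the co-pollutant study mode)?
#' @return List with `grid`, `landuse`, `ndvi`, `meteo`, `stations`,
#'   `design` (a `lur_design` with response filled), `truth` (with the
#'   calibrated `noise_sd`), and `pm` (the [generate_pm25()] output,
#'   including the noiseless predictor).
#' @export
simulate_lur_study <- function(seed, grid = grid_spec(),
                               n_stations = 17,
                               start = "2016-01", n_months = 36,
                               classes = c(Residential = 0.45,
                                           Commercial = 0.15,
                                           Industrial = 0.10),
                               ladder = c(250, 500, 1000, 1500, 2000,
                                          3000, 4000, 5000),
                               truth = NULL, target_r2 = 0.8,
                               n_meteo_stations = 5,
                               copollutants = FALSE) {
  seed <- as.integer(seed)
  periods <- month_seq(start, n_months)
  keys <- sprintf("%d-%02d", periods$year, periods$month)
  landuse <- generate_landuse(seed + 1L, grid, classes)
  ndvi <- generate_ndvi(seed + 2L, grid, keys)
  last <- as.Date(paste0(keys[n_months], "-01"))
  dates <- seq(as.Date(paste0(start, "-01")),
               seq(last, by = "month", length.out = 2)[2] - 1, by = "day")
  meteo <- generate_meteo(seed + 3L, grid, n_meteo_stations, dates)
  stations <- with_seed(seed, {
    cells <- sample(grid$n_rows * grid$n_cols, n_stations)
    i <- ((cells - 1L) %% grid$n_rows) + 1L
    j <- ((cells - 1L) %/% grid$n_rows) + 1L
    cbind(data.frame(station_id = sprintf("pm%02d", seq_len(n_stations))),
          cell_center(grid, i, j))
  })
  feats <- station_buffer_features(landuse, ndvi$composites, stations, ladder)
  static <- feats$static
  for (lay in c("Airport", "MajorRoad")) {
    static[[sprintf("%s_nearest", lay)]] <-
      nearest_distance(landuse$vectors[landuse$vectors$layer == lay, ],
                       stations)
  }
  monthly <- merge(feats$monthly,
                   monitor_meteo_monthly(meteo, stations, periods),
                   by = c("station_id", "year", "month"))
  if (copollutants) {
    monthly <- merge(monthly, generate_copollutants(seed + 5L, stations, periods),
                     by = c("station_id", "year", "month"))
  }
  design <- assemble_design(stations, periods, static, monthly)
  if (is.null(truth)) truth <- default_truth(seed + 4L)
  missing <- setdiff(names(truth$coefficients), design$candidates$name)
  if (length(missing) > 0) {
    stop("ground-truth variables not among candidates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(target_r2) &&
      (is.na(truth$noise_sd) || truth$noise_sd == 0)) {
    lp <- generate_pm25(ground_truth(truth$intercept, truth$coefficients, 0,
                                     truth$seed), design$data)$noiseless
    truth$noise_sd <- noise_for_r2(lp, target_r2)
  }
  pm <- generate_pm25(truth, design$data)
  design <- set_response(design, pm$pm25)
  list(grid = grid, landuse = landuse, ndvi = ndvi, meteo = meteo,
       stations = stations, design = design, truth = truth, pm = pm)
}

#' Simulate a fixed-size synthetic design matrix
#'
#' Convenience wrapper around [simulate_lur_study()] for multi-seed
#' selection experiments: a 100 x 100-cell scene, 17 monitors, 30
#' months (about 510 station-month rows) trimmed to exactly `n_obs`
#' rows in (period, station) order. The default candidate set has 40
#' predictors: 3 land-use classes and NDVI over an 8-radius ladder,
#' 4 meteorology variables, 2 nearest distances and 2 season dummies.
#'
#' @param seed Master seed.
#' @param n_obs Number of design rows to keep (default 500).
#' @param ... Passed on to [simulate_lur_study()].
#' @return As [simulate_lur_study()], with trimmed `design` and `pm`.
#' @export
simulate_lur_dataset <- function(seed, n_obs = 500, ...) {
  study <- simulate_lur_study(seed, grid = grid_spec(0, 0, 50, 100, 100),
                              n_months = 30, ...)
  stopifnot(nrow(study$design$data) >= n_obs)
  keep <- seq_len(n_obs)
  study$design$data <- study$design$data[keep, , drop = FALSE]
  study$pm <- lapply(study$pm, `[`, keep)
  study
}
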