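# Seeded synthetic scenes: spatially structured land use, smooth NDVI with a
# 16-day cadence, station meteorology with spatial gradients and seasonal
# cycles, and monitor PM2.5 drawn from a known linear ground-truth model.
# Everything is deterministic given (seed, parameters).

# Smooth standardized Gaussian random field: white noise blurred by a
# separable Gaussian kernel, then rescaled to mean 0, sd 1.
gaussian_field <- function(n_rows, n_cols, range_cells = 10) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  sigma <- range_cells / 2
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  sm <- blur_separable_cpp(z, k / sum(k))
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic land-use scene
#'
#' Classifies a smooth Gaussian random field by its empirical quantiles so
#' that each requested class occupies (almost exactly) its target area
#' fraction while remaining spatially contiguous. Cells not assigned to a
#' listed class get code 0 ("other"). Also generates simple vector
#' features inside the grid bounds: two major-road chords, one railway
#' chord, one airport point, and two quarry-site points.
#'
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param grid A [grid_spec()].
#' @param classes Named numeric vector of target area fractions
#'   (non-negative, summing to at most 1).
#' @param range_cells Spatial correlation range of the underlying field,
#'   in cells.
#' @return List with `raster` (class-coded [feature_raster()]), `classes`
#'   (named integer codes), `fractions` (targets), and `vectors`
#'   (a [vector_features()] data.frame).
#' @export
generate_landuse <- function(seed, grid,
                             classes = c(Residential = 0.45, Commercial = 0.15,
                                         Industrial = 0.10),
                             range_cells = 12) {
  if (length(classes) == 0) stop("empty class list", call. = FALSE)
  if (any(classes < 0) || sum(classes) > 1 + 1e-12) {
    stop("class fractions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  with_seed(seed, {
    field <- gaussian_field(grid$n_rows, grid$n_cols, range_cells)
    n <- length(field)
    ord <- order(field)            # ties impossible a.s.; order is stable
    codes <- integer(n)
    counts <- round(classes * n)
    stopifnot(sum(counts) <= n)
    pos <- 0L
    for (k in seq_along(classes)) {
      if (counts[k] > 0) codes[ord[(pos + 1L):(pos + counts[k])]] <- k
      pos <- pos + counts[k]
    }
    raster <- feature_raster(grid, matrix(codes, grid$n_rows, grid$n_cols),
                             name = "landuse", units = "class")
    xmin <- grid$origin_x; xmax <- grid$origin_x + grid$n_cols * grid$cell_size
    ymin <- grid$origin_y; ymax <- grid$origin_y + grid$n_rows * grid$cell_size
    chord <- function() {
      # a line between random points on two distinct edges
      e <- sample(4, 2)
      pt <- function(edge) switch(edge,
        c(runif(1, xmin, xmax), ymin), c(runif(1, xmin, xmax), ymax),
        c(xmin, runif(1, ymin, ymax)), c(xmax, runif(1, ymin, ymax)))
      a <- pt(e[1]); b <- pt(e[2])
      sprintf("LINESTRING (%f %f, %f %f)", a[1], a[2], b[1], b[2])
    }
    pointw <- function() sprintf("POINT (%f %f)", runif(1, xmin, xmax),
                                 runif(1, ymin, ymax))
    vectors <- vector_features(
      layer = c("MajorRoad", "MajorRoad", "Railway", "Airport",
                "Quarry", "Quarry"),
      wkt = c(chord(), chord(), chord(), pointw(), pointw(), pointw())
    )
    list(raster = raster,
         classes = setNames(seq_along(classes), names(classes)),
         fractions = classes, vectors = vectors)
  })
}

# day-of-year start of each 16-day compositing period within a year
cadence_starts <- function() seq(1, 353, by = 16)

days_in_month <- function(year, month) {
  as.integer(format(seq(as.Date(sprintf("%d-%02d-01", year, month)),
                        by = "month", length.out = 2)[2] - 1, "%d"))
}

#' Monthly composite of 16-day NDVI layers
#'
#' Combines the 16-day layers whose date range overlaps a calendar month
#' into one monthly raster, by cellwise maximum (the max-value-composite
#' convention of satellite vegetation products) or mean.
#'
#' @param layers List of layers, each a list with `year`, `start_doy`,
#'   and `raster` (a [feature_raster()]). A layer starting at day-of-year
#'   `d` covers days `d .. min(d + 15, last day of year)`.
#' @param year,month Target period.
#' @param method `"max"` (default) or `"mean"`.
#' @return A [feature_raster()] named `NDVI`.
#' @export
ndvi_composite <- function(layers, year, month, method = c("max", "mean")) {
  method <- match.arg(method)
  first <- as.integer(format(as.Date(sprintf("%d-%02d-01", year, month)), "%j"))
  last <- first + days_in_month(year, month) - 1L
  days_in_year <- as.integer(format(as.Date(sprintf("%d-12-31", year)), "%j"))
  use <- Filter(function(l) {
    l$year == year &&
      l$start_doy <= last && min(l$start_doy + 15L, days_in_year) >= first
  }, layers)
  if (length(use) == 0) stop(sprintf("no NDVI layers overlap %d-%02d", year, month),
                             call. = FALSE)
  mats <- lapply(use, function(l) l$raster$values)
  vals <- if (method == "max") Reduce(pmax, mats) else Reduce(`+`, mats) / length(mats)
  feature_raster(use[[1]]$raster$grid, vals, name = "NDVI", units = "index")
}

#' Generate a synthetic NDVI stack
#'
#' Produces spatially smooth NDVI fields on the grid at the 16-day
#' cadence of satellite vegetation-index composites, plus monthly
#' composites. Each layer is a fixed smooth base field plus a seasonal
#' cycle and a small per-layer smooth perturbation, clamped to `[-1, 1]`.
#'
#' @inheritParams generate_landuse
#' @param months Character vector of periods `"YYYY-MM"` (at least one).
#' @param base_mean Mean NDVI of the scene.
#' @param spatial_sd Standard deviation of the static spatial field.
#' @param seasonal_amp Amplitude of the seasonal cycle (index units).
#' @param peak_doy Day of year at which NDVI peaks (default 140, a
#'   post-wet-season greenness peak distinct from the humidity and
#'   temperature phases).
#' @param noise_sd Standard deviation of the per-layer smooth perturbation.
#' @param anomaly_sd Standard deviation of a yearly greenness anomaly.
#' @param range_cells Spatial correlation range in cells.
#' @param composite `"max"` or `"mean"` monthly compositing.
#' @return List with `layers` (16-day layers) and `composites` (named
#'   list of monthly [feature_raster()]s keyed `"YYYY-MM"`).
#' @export
generate_ndvi <- function(seed, grid, months,
                          base_mean = 0.25, spatial_sd = 0.09,
                          seasonal_amp = 0.03, peak_doy = 140, noise_sd = 0.025,
                          anomaly_sd = 0.02, range_cells = 10,
                          composite = c("max", "mean")) {
  composite <- match.arg(composite)
  if (length(months) == 0) stop("at least one period required", call. = FALSE)
  per <- do.call(rbind, lapply(strsplit(months, "-"), as.integer))
  years <- sort(unique(per[, 1]))
  with_seed(seed, {
    base <- base_mean + spatial_sd * gaussian_field(grid$n_rows, grid$n_cols,
                                                    range_cells)
    layers <- list()
    anom <- setNames(rnorm(length(years), 0, anomaly_sd), years)
    for (yr in years) {
      for (d in cadence_starts()) {
        season <- seasonal_amp * cos(2 * pi * (d + 8 - peak_doy) / 365) +
          anom[[as.character(yr)]]
        pert <- if (noise_sd > 0) {
          noise_sd * gaussian_field(grid$n_rows, grid$n_cols, range_cells)
        } else 0
        vals <- pmin(pmax(base + season + pert, -1), 1)
        layers[[length(layers) + 1L]] <-
          list(year = yr, start_doy = d,
               raster = feature_raster(grid, vals, name = "NDVI",
                                       units = "index"))
      }
    }
    composites <- list()
    for (r in seq_len(nrow(per))) {
      key <- sprintf("%d-%02d", per[r, 1], per[r, 2])
      composites[[key]] <- ndvi_composite(layers, per[r, 1], per[r, 2],
                                          method = composite)
    }
    list(layers = layers, composites = composites)
  })
}

# per-variable defaults for synthetic meteorology: base level, spatial
# gradient half-range, station-level micro-siting offset sd, seasonal
# amplitude, peak day-of-year, monthly-anomaly sd, yearly-anomaly sd, and
# daily noise sd. The monthly/yearly anomalies and local offsets are what
# keep different variables (all sharing the annual frequency and the same
# 5-station interpolation geometry) from being collinear at monthly scale.
meteo_defaults <- function() {
  list(
    temperature       = list(base = 31.5, spatial = 1.5, local = 0.5, amp = 0.8, peak = 260, monthly = 0.6, anomaly = 0.4, noise = 0.7),
    relative_humidity = list(base = 78,   spatial = 6,   local = 2.5, amp = 3.5, peak = 20,  monthly = 3,   anomaly = 1.5, noise = 3),
    wind_speed        = list(base = 2.5,  spatial = 0.8, local = 0.3, amp = 0.6, peak = 200, monthly = 0.4, anomaly = 0.3, noise = 0.8),
    wind_direction    = list(base = 180,  spatial = 40,  local = 15,  amp = 60,  peak = 30,  monthly = 15,  anomaly = 10,  noise = 30),
    rainfall          = list(base = 6,    spatial = 2,   local = 1,   amp = 5,   peak = 90,  monthly = 3,   anomaly = 1.5, noise = 5),
    uv                = list(base = 6,    spatial = 1,   local = 0.4, amp = 1.5, peak = 260, monthly = 0.8, anomaly = 0.5, noise = 1.2)
  )
}

#' Generate synthetic daily station meteorology
#'
#' Each variable is a station-specific level (a linear spatial gradient
#' with a random orientation) plus a sinusoidal seasonal cycle, a yearly
#' anomaly (inter-annual variation), and iid daily noise. Relative
#' humidity is clamped to `[0, 100]`; wind speed, rainfall and UV are
#' floored at 0; wind direction is wrapped to `[0, 360)`.
#'
#' @inheritParams generate_landuse
#' @param n_stations Number of meteorology stations (distinct cells).
#' @param dates Vector of `Date`s for the daily series.
#' @param params Per-variable parameter lists (see `meteo_defaults`
#'   internal): `base`, `spatial`, `amp`, `peak`, `noise`.
#' @return Long data.frame: `station_id`, `x`, `y`, `date`, `variable`,
#'   `value`.
#' @export
generate_meteo <- function(seed, grid, n_stations = 5, dates,
                           params = meteo_defaults()) {
  stopifnot(n_stations >= 1)
  n_cells <- grid$n_rows * grid$n_cols
  if (n_stations > n_cells) {
    stop("more meteorology stations than grid cells", call. = FALSE)
  }
  with_seed(seed, {
    cells <- sample(n_cells, n_stations)
    i <- ((cells - 1L) %% grid$n_rows) + 1L
    j <- ((cells - 1L) %/% grid$n_rows) + 1L
    cc <- cell_center(grid, i, j)
    # standardized coordinates in [-1, 1] for the gradients
    ux <- 2 * (cc$x - grid$origin_x) / (grid$n_cols * grid$cell_size) - 1
    uy <- 2 * (cc$y - grid$origin_y) / (grid$n_rows * grid$cell_size) - 1
    doy <- as.integer(format(dates, "%j"))
    yr <- as.integer(format(dates, "%Y"))
    ym <- format(dates, "%Y-%m")
    yr_levels <- sort(unique(yr))
    ym_levels <- sort(unique(ym))
    out <- vector("list", length(params))
    opt <- function(p, nm) if (is.null(p[[nm]])) 0 else p[[nm]]
    for (v in seq_along(params)) {
      p <- params[[v]]
      theta <- runif(1, 0, 2 * pi)
      level <- p$base + p$spatial * (cos(theta) * ux + sin(theta) * uy) +
        rnorm(n_stations, 0, opt(p, "local"))
      yr_anom <- setNames(rnorm(length(yr_levels), 0, opt(p, "anomaly")),
                          yr_levels)
      mo_anom <- setNames(rnorm(length(ym_levels), 0, opt(p, "monthly")),
                          ym_levels)
      season <- p$amp * cos(2 * pi * (doy - p$peak) / 365) +
        yr_anom[as.character(yr)] + mo_anom[ym]
      vals <- outer(season, level, `+`) +
        matrix(rnorm(length(dates) * n_stations, sd = p$noise),
               length(dates), n_stations)
      nm <- names(params)[v]
      if (nm == "relative_humidity") vals <- pmin(100, pmax(0, vals))
      if (nm %in% c("wind_speed", "rainfall", "uv")) vals <- pmax(0, vals)
      if (nm == "wind_direction") vals <- vals %% 360
      out[[v]] <- data.frame(
        station_id = rep(sprintf("met%02d", seq_len(n_stations)),
                         each = length(dates)),
        x = rep(cc$x, each = length(dates)),
        y = rep(cc$y, each = length(dates)),
        date = rep(dates, n_stations),
        variable = nm,
        value = as.vector(vals),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Ground-truth linear model for synthetic PM2.5
#'
#' The data-generating model `Y = b0 + sum_i b_i X_i + e`,
#' `e ~ Normal(0, noise_sd)`, used to draw monitor PM2.5 from a design of
#' candidate predictors and to benchmark parameter recovery.
#'
#' @param intercept Intercept `b0` in ug/m3.
#' @param coefficients Named numeric vector of true coefficients; names
#'   must match design-matrix columns.
#' @param noise_sd Residual standard deviation (>= 0), ug/m3.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(intercept, coefficients, noise_sd, seed = 1L) {
  stopifnot(noise_sd >= 0, length(coefficients) >= 0,
            !is.null(names(coefficients)) || length(coefficients) == 0)
  structure(list(intercept = intercept, coefficients = coefficients,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Draw PM2.5 observations from a ground-truth model
#'
#' Computes the noiseless linear predictor from the design columns, adds
#' Gaussian noise, and truncates at 0 (concentrations cannot be
#' negative). The exact noiseless values and the untruncated draws are
#' returned so downstream tests need not fight the truncation.
#'
#' @param truth A [ground_truth()].
#' @param design A data.frame containing every column named in
#'   `truth$coefficients`.
#' @return List with `pm25` (truncated), `raw` (untruncated draws) and
#'   `noiseless` (exact linear predictor).
#' @export
generate_pm25 <- function(truth, design) {
  vars <- names(truth$coefficients)
  missing <- setdiff(vars, names(design))
  if (length(missing) > 0) {
    stop("design is missing ground-truth columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- rep(truth$intercept, NROW(design))
  if (length(vars) > 0) {
    lp <- lp + as.vector(as.matrix(design[vars]) %*% truth$coefficients)
  }
  raw <- with_seed(truth$seed,
                   lp + rnorm(NROW(design), sd = truth$noise_sd))
  list(pm25 = pmax(0, raw), raw = raw, noiseless = lp)
}

#' Residual noise level for a target coefficient of determination
#'
#' Given a noiseless linear predictor, returns the residual standard
#' deviation that makes the population R-squared of the true model equal
#' `r2`: `noise_sd = sd(lp) * sqrt(1/r2 - 1)`.
#'
#' @param lp Noiseless linear predictor values.
#' @param r2 Target R-squared in (0, 1].
#' @return Residual standard deviation.
#' @export
noise_for_r2 <- function(lp, r2) {
  stopifnot(r2 > 0, r2 <= 1)
  sd(lp) * sqrt(1 / r2 - 1)
}
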