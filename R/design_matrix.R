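# Station-month design matrices: monthly aggregation of daily series,
# season indicator encoding, a-priori effect directions, and assembly of
# the response + candidate-predictor table the selection engine consumes.

#' Aggregate a daily series to monthly means
#'
#' A month is emitted only if the fraction of its calendar days with a
#' non-missing value is at least `min_completeness`; its value is the
#' arithmetic mean of the available days.
#'
#' @param dates Vector of `Date`s.
#' @param values Numeric values aligned with `dates` (may contain `NA`).
#' @param min_completeness Minimum fraction of days required (0, 1].
#' @return data.frame with columns `year`, `month`, `value`.
#' @export
monthly_mean <- function(dates, values, min_completeness = 0.75) {
  if (length(dates) == 0) stop("empty series", call. = FALSE)
  stopifnot(length(dates) == length(values),
            min_completeness > 0, min_completeness <= 1)
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  key <- sprintf("%d-%02d", yr, mo)
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    y <- yr[sel][1]; m <- mo[sel][1]
    present <- sum(!is.na(values[sel]))
    if (present / days_in_month(y, m) < min_completeness) return(NULL)
    data.frame(year = y, month = m, value = mean(values[sel], na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(year = integer(), month = integer(), value = numeric())
  }
  out[order(out$year, out$month), , drop = FALSE]
}

#' Season definition
#'
#' A named partition of calendar months into seasons used for the 0/1
#' season indicators. The default is the northern-hemisphere
#' meteorological convention for the two seasons the models use:
#' spring = March-May, fall = September-November.
#'
#' @param ... Named integer vectors of months (1-12), e.g.
#'   `Spring = 3:5, Fall = 9:11`. Months may not repeat across seasons.
#' @return Named list of class `season_scheme`.
#' @export
season_scheme <- function(Spring = 3:5, Fall = 9:11, ...) {
  sch <- c(list(Spring = Spring, Fall = Fall), list(...))
  sch <- sch[!vapply(sch, is.null, logical(1))]
  all_m <- unlist(sch)
  if (any(all_m < 1 | all_m > 12)) stop("months must be in 1-12", call. = FALSE)
  if (anyDuplicated(all_m)) {
    stop("season scheme must not assign a month to two seasons", call. = FALSE)
  }
  structure(sch, class = "season_scheme")
}

#' Season indicator variables
#'
#' @param month Integer month(s) in 1-12 (vectorised).
#' @param scheme A [season_scheme()].
#' @return data.frame with one 0/1 column per season; at most one
#'   indicator is active per row.
#' @export
season_dummies <- function(month, scheme = season_scheme()) {
  if (!inherits(scheme, "season_scheme")) stop("unknown season scheme", call. = FALSE)
  if (any(month < 1 | month > 12)) stop("month must be in 1-12", call. = FALSE)
  out <- lapply(scheme, function(ms) as.integer(month %in% ms))
  as.data.frame(out)
}

# ---- candidate variables -------------------------------------------------

meteo_var_names <- c(Temperature = "temperature",
                     RelativeHumidity = "relative_humidity",
                     WindSpeed = "wind_speed",
                     WindDirection = "wind_direction",
                     Rainfall = "rainfall", UV = "uv")
copollutant_names <- c("PM10", "NO2", "SO2")
builtup_layers <- c("Residential", "Commercial", "Industrial", "MajorRoad",
                    "Railway", "Airport", "Quarry", "Port", "Traffic")

classify_variable <- function(name) {
  p <- parse_feature_name(name)
  vapply(seq_along(name), function(k) {
    if (!is.na(p$radius[k])) {
      if (p$layer[k] == "NDVI") "ndvi" else "land_use"
    } else if (grepl("_nearest$", name[k])) "distance"
    else if (name[k] %in% copollutant_names) "copollutant"
    else if (name[k] %in% c("Spring", "Summer", "Fall", "Winter")) "season"
    else "meteorology"
  }, character(1))
}

#' Default a-priori effect directions
#'
#' The sign each candidate's coefficient is expected to take: positive
#' for built/transport/industrial/quarry land-use buffers, co-pollutants,
#' temperature and spring; negative for NDVI, relative humidity,
#' rainfall, UV, fall, and airport nearest-distance; 0 (unconstrained)
#' for anything else. Fully overridable when assembling a design.
#'
#' @param name Character vector of candidate names.
#' @return Integer vector in `{-1, 0, 1}` named by `name`.
#' @export
default_direction_priors <- function(name) {
  p <- parse_feature_name(name)
  prior <- integer(length(name))
  pos_exact <- c("Temperature", "Spring", copollutant_names)
  neg_exact <- c("RelativeHumidity", "Rainfall", "UV", "Fall",
                 "Airport_nearest")
  prior[name %in% pos_exact] <- 1L
  prior[name %in% neg_exact] <- -1L
  buffer <- !is.na(p$radius)
  prior[buffer & p$layer %in% builtup_layers] <- 1L
  prior[buffer & p$layer == "NDVI"] <- -1L
  setNames(prior, name)
}

#' Candidate-variable metadata table
#'
#' @param name Candidate names (design-matrix columns).
#' @param direction_prior Optional named overrides in `{-1, 0, 1}`;
#'   defaults from [default_direction_priors()].
#' @return data.frame with columns `name`, `var_class`, `radius`,
#'   `direction_prior`.
#' @export
candidate_table <- function(name, direction_prior = NULL) {
  pr <- default_direction_priors(name)
  if (!is.null(direction_prior)) {
    bad <- setdiff(names(direction_prior), name)
    if (length(bad)) stop("prior overrides for unknown variables: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    pr[names(direction_prior)] <- as.integer(direction_prior)
  }
  data.frame(name = name,
             var_class = classify_variable(name),
             radius = parse_feature_name(name)$radius,
             direction_prior = as.integer(pr),
             stringsAsFactors = FALSE)
}

# ---- design assembly -----------------------------------------------------

#' Assemble a station-month design matrix
#'
#' Joins static buffer features (constant over time per station),
#' monthly features (NDVI composites, interpolated meteorology, optional
#' co-pollutants) and season indicators into one observation table keyed
#' by (station, year, month), together with candidate metadata. Rows
#' with a missing response are dropped with a message.
#'
#' @param stations data.frame with `station_id`, `x`, `y`.
#' @param periods data.frame with `year`, `month`.
#' @param static_features data.frame keyed by `station_id` with one
#'   column per static candidate (land-use buffers, nearest distances).
#' @param monthly_features Optional data.frame keyed by
#'   (`station_id`, `year`, `month`) with time-varying candidates
#'   (NDVI buffers, meteorology, co-pollutants).
#' @param response Optional numeric response (PM2.5, ug/m3) aligned with
#'   the expanded station x period rows, or a data.frame keyed by
#'   (`station_id`, `year`, `month`) with column `pm25`.
#' @param scheme A [season_scheme()] for the season indicators.
#' @param direction_prior Optional named prior overrides.
#' @return An object of class `lur_design`: list with `data` (the
#'   observation table) and `candidates` (metadata).
#' @export
assemble_design <- function(stations, periods, static_features = NULL,
                            monthly_features = NULL, response = NULL,
                            scheme = season_scheme(),
                            direction_prior = NULL) {
  base <- merge(stations, periods, by = NULL)  # cartesian station x period
  base <- base[order(base$year, base$month, base$station_id), , drop = FALSE]
  rownames(base) <- NULL
  if (!is.null(static_features)) {
    if (anyDuplicated(static_features$station_id)) {
      stop("static_features must have one row per station", call. = FALSE)
    }
    base <- merge(base, static_features, by = "station_id", sort = FALSE)
  }
  if (!is.null(monthly_features)) {
    base <- merge(base, monthly_features,
                  by = c("station_id", "year", "month"), sort = FALSE)
  }
  sd_cols <- season_dummies(base$month, scheme)
  base <- cbind(base, sd_cols)
  base <- base[order(base$year, base$month, base$station_id), , drop = FALSE]
  rownames(base) <- NULL
  if (anyDuplicated(base[c("station_id", "year", "month")])) {
    stop("duplicate (station, period) rows in design", call. = FALSE)
  }
  cand_names <- setdiff(names(base),
                        c("station_id", "x", "y", "year", "month", "pm25"))
  if (!is.null(response)) {
    if (is.data.frame(response)) {
      base <- merge(base, response[c("station_id", "year", "month", "pm25")],
                    by = c("station_id", "year", "month"), sort = FALSE)
      base <- base[order(base$year, base$month, base$station_id), , drop = FALSE]
      rownames(base) <- NULL
    } else {
      stopifnot(length(response) == nrow(base))
      base$pm25 <- response
    }
    n_miss <- sum(is.na(base$pm25))
    if (n_miss > 0) {
      message(sprintf("dropping %d rows with missing response", n_miss))
      base <- base[!is.na(base$pm25), , drop = FALSE]
    }
  } else {
    base$pm25 <- NA_real_
  }
  structure(list(data = base,
                 candidates = candidate_table(cand_names, direction_prior),
                 response = "pm25"),
            class = "lur_design")
}

#' @export
print.lur_design <- function(x, ...) {
  cat(sprintf("<lur_design> %d station-month rows, %d candidate predictors\n",
              nrow(x$data), nrow(x$candidates)))
  tab <- table(x$candidates$var_class)
  cat("  candidates by class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Set or replace the response of a design
#'
#' @param design A `lur_design`.
#' @param pm25 Numeric response aligned with `design$data` rows.
#' @return The design with response filled (missing-response rows kept;
#'   they are dropped by the fitting functions).
#' @export
set_response <- function(design, pm25) {
  stopifnot(inherits(design, "lur_design"), length(pm25) == nrow(design$data))
  design$data$pm25 <- pm25
  design
}
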