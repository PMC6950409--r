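# Validation and prediction: k-fold cross-validation of the fitted (or
# re-selected) model, gridded prediction surfaces from the regression
# equation, period averaging, and air-quality-guideline exceedance counts.

#' k-fold cross-validation of a LUR model
#'
#' Randomly partitions the station-month observations into `k` folds of
#' near-equal size (a seeded assignment), trains on `k - 1` folds and
#' predicts the held-out fold. By default the term set of `model` is
#' held fixed and only coefficients are re-estimated per fold;
#' `refit_selection = TRUE` re-runs the full supervised stepwise
#' selection inside each training split. The headline metrics are
#' pooled over the concatenated out-of-fold predictions.
#'
#' @param design A `lur_design` with response filled.
#' @param model A `lur_model` whose terms are cross-validated (ignored
#'   when `refit_selection = TRUE`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param refit_selection Re-run selection within each training fold?
#' @param p_enter,vif_max Gates used when re-selecting.
#' @return A list of class `cv_result`: `k`, `folds` (assignment per
#'   row), `per_fold` (data.frame of per-fold n, R2, RMSE), pooled `r2`,
#'   `adj_r2`, `rmse`, and `predictions` (observed vs out-of-fold
#'   predicted).
#' @export
kfold_cv <- function(design, model = NULL, k = 10, seed = 1,
                     refit_selection = FALSE, p_enter = 0.1, vif_max = 3) {
  df <- design_data(design)
  df <- df[!is.na(df$pm25), , drop = FALSE]
  n <- nrow(df)
  if (n < 2 * k) stop("need at least 2k observations for k folds", call. = FALSE)
  if (!refit_selection && is.null(model)) {
    stop("supply a fitted model or set refit_selection = TRUE", call. = FALSE)
  }
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- rep(NA_real_, n)
  sizes <- integer(k)
  per_fold <- vector("list", k)
  n_terms <- if (!is.null(model)) nrow(model$terms) else NA_integer_
  for (f in seq_len(k)) {
    train <- folds != f
    sizes[f] <- sum(!train)
    sub <- design
    sub$data <- df[train, , drop = FALSE]
    terms <- if (refit_selection) {
      m <- supervised_stepwise(sub, p_enter = p_enter, vif_max = vif_max)
      m$terms$name
    } else model$terms$name
    if (sum(train) < length(terms) + 2) {
      stop(sprintf(paste("fold %d has %d training rows for a %d-term model;",
                         "use fewer terms or fewer folds"),
                   f, sum(train), length(terms)), call. = FALSE)
    }
    fit <- fit_ols(sub, terms)
    Xt <- cbind(1, as.matrix(df[!train, terms, drop = FALSE]))
    pred[!train] <- as.vector(Xt %*% fit$coefficients)
    obs <- df$pm25[!train]
    sse <- sum((obs - pred[!train])^2)
    sst <- sum((obs - mean(obs))^2)
    per_fold[[f]] <- data.frame(fold = f, n = sizes[f],
                                r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                                rmse = sqrt(sse / sizes[f]))
  }
  obs <- df$pm25
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- 1 - sse / sst
  k_model <- if (refit_selection) NA_integer_ else n_terms
  adj <- if (!is.na(k_model)) 1 - (1 - r2) * (n - 1) / (n - k_model - 1)
         else NA_real_
  structure(list(k = k, folds = folds, per_fold = do.call(rbind, per_fold),
                 r2 = r2, adj_r2 = adj, rmse = sqrt(sse / n),
                 predictions = data.frame(station_id = df$station_id,
                                          year = df$year, month = df$month,
                                          observed = obs, predicted = pred,
                                          fold = folds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: pooled R2=%.3f, RMSE=%.2f\n",
              x$k, x$r2, x$rmse))
  print(x$per_fold, digits = 3)
  invisible(x)
}

#' Predict a PM2.5 surface from the regression equation
#'
#' Evaluates `b0 + sum_i b_i X_i(cell)` on the grid, given one predictor
#' raster per model term (static layers may be reused across periods).
#' Negative cells can optionally be floored at 0 for map export; the
#' number of floored cells is recorded in attribute `n_floored`.
#'
#' @param model A `lur_model`.
#' @param rasters Named list of [feature_raster()]s covering every term.
#' @param period Period label (`"YYYY-MM"`, `"YYYY"`, or `"pooled"`).
#' @param floor_at_zero Truncate negative predictions at 0?
#' @return A [feature_raster()] of predicted PM2.5 (ug/m3).
#' @export
predict_surface <- function(model, rasters, period = "pooled",
                            floor_at_zero = FALSE) {
  need <- model$terms$name
  missing <- setdiff(need, names(rasters))
  if (length(missing) > 0) {
    stop("missing predictor raster for term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grid <- if (length(need) > 0) rasters[[need[1]]]$grid
          else rasters[[1]]$grid
  vals <- matrix(model$intercept, grid$n_rows, grid$n_cols)
  for (i in seq_along(need)) {
    r <- rasters[[need[i]]]
    if (!grid_equal(r$grid, grid)) stop("predictor raster grids differ",
                                        call. = FALSE)
    vals <- vals + model$terms$beta[i] * r$values
  }
  n_floored <- 0L
  if (floor_at_zero) {
    n_floored <- sum(vals < 0, na.rm = TRUE)
    vals <- pmax(vals, 0)
  }
  out <- feature_raster(grid, vals, name = sprintf("PM25_%s", period),
                        units = "ug/m3")
  attr(out, "period") <- period
  attr(out, "n_floored") <- n_floored
  out
}

#' Average monthly surfaces over a period
#'
#' Cellwise arithmetic mean of the supplied monthly rasters (e.g. one
#' calendar year, or all months pooled).
#'
#' @param rasters Non-empty list of [feature_raster()]s on one grid.
#' @param period Label for the averaged surface (`"YYYY"` or `"pooled"`).
#' @return A [feature_raster()].
#' @export
period_average <- function(rasters, period = "pooled") {
  if (length(rasters) == 0) stop("no rasters in period", call. = FALSE)
  grid <- rasters[[1]]$grid
  for (r in rasters) {
    if (!grid_equal(r$grid, grid)) stop("raster grids differ", call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(rasters, `[[`, "values")) / length(rasters)
  out <- feature_raster(grid, vals, name = sprintf("PM25_%s", period),
                        units = "ug/m3")
  attr(out, "period") <- period
  out
}

#' Default air-quality-guideline thresholds
#'
#' WHO guideline values of 10 (annual) and 25 (24-hour) ug/m3 and the
#' Indonesian national standards of 15 (annual) and 65 (24-hour) ug/m3.
#'
#' @return Named numeric vector of thresholds in ug/m3.
#' @export
aqg_thresholds <- function() {
  c(WHO_annual = 10, WHO_24h = 25, Indonesia_annual = 15, Indonesia_24h = 65)
}

#' Guideline exceedance summary of a prediction surface
#'
#' Counts grid cells whose predicted concentration exceeds each named
#' threshold (strictly greater), with fractions over non-missing cells.
#'
#' @param raster A [feature_raster()] of PM2.5 predictions.
#' @param thresholds Named positive thresholds in ug/m3
#'   (default [aqg_thresholds()]).
#' @return data.frame with columns `threshold_name`, `threshold`,
#'   `n_exceed`, `n_cells`, `fraction`.
#' @export
exceedance_summary <- function(raster, thresholds = aqg_thresholds()) {
  stopifnot(all(thresholds > 0))
  v <- raster$values[!is.na(raster$values)]
  n <- length(v)
  data.frame(threshold_name = names(thresholds),
             threshold = unname(thresholds),
             n_exceed = vapply(thresholds, function(t) sum(v > t), integer(1)),
             n_cells = n,
             fraction = vapply(thresholds, function(t) mean(v > t), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
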