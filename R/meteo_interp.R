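#' Inverse-distance-weighting configuration
#'
#' @param power Distance-decay exponent (> 0). Default 2, the
#'   conventional IDW choice.
#' @param max_neighbors Number of nearest stations to use, or `Inf` for
#'   all (the default — LUR study areas typically have few stations).
#' @param snap_tolerance Queries within this distance (meters) of a
#'   station return that station's value exactly, avoiding division by
#'   zero at coincident points.
#' @return A list of class `idw_config`.
#' @export
idw_config <- function(power = 2, max_neighbors = Inf, snap_tolerance = 1) {
  stopifnot(power > 0, snap_tolerance >= 0,
            is.infinite(max_neighbors) || max_neighbors >= 1)
  structure(list(power = power, max_neighbors = max_neighbors,
                 snap_tolerance = snap_tolerance), class = "idw_config")
}

#' Inverse-distance-weighted interpolation at query points
#'
#' Interpolates station values to arbitrary coordinates with weights
#' `w_i = d_i^(-power)`. The result is a convex combination of station
#' values, so it always lies within their range, and it reproduces
#' station values exactly at (or within `snap_tolerance` of) station
#' locations.
#'
#' @param stations data.frame with columns `x`, `y`, `value`.
#' @param query data.frame with columns `x`, `y`.
#' @param cfg An [idw_config()].
#' @return Numeric vector of interpolated values, one per query row.
#' @export
idw <- function(stations, query, cfg = idw_config()) {
  ok <- is.finite(stations$value)
  if (!any(ok)) stop("no stations with finite values", call. = FALSE)
  sx <- stations$x[ok]; sy <- stations$y[ok]; sv <- stations$value[ok]
  n <- NROW(query)
  out <- numeric(n)
  for (q in seq_len(n)) {
    d <- sqrt((sx - query$x[q])^2 + (sy - query$y[q])^2)
    near <- which.min(d)
    if (d[near] <= cfg$snap_tolerance) {
      out[q] <- sv[near]
      next
    }
    use <- seq_along(d)
    if (is.finite(cfg$max_neighbors) && cfg$max_neighbors < length(d)) {
      use <- order(d)[seq_len(cfg$max_neighbors)]
    }
    w <- d[use]^(-cfg$power)
    out[q] <- sum(w * sv[use]) / sum(w)
  }
  out
}

#' IDW interpolation onto a grid
#'
#' Evaluates [idw()] at every cell center; matches the point-wise
#' operator exactly.
#'
#' @inheritParams idw
#' @param grid A [grid_spec()].
#' @param name Output layer name.
#' @param units Unit label.
#' @return A [feature_raster()].
#' @export
idw_surface <- function(stations, grid, cfg = idw_config(), name = "idw",
                        units = "") {
  centers <- cell_center(grid,
                         i = rep(seq_len(grid$n_rows), times = grid$n_cols),
                         j = rep(seq_len(grid$n_cols), each = grid$n_rows))
  v <- idw(stations, centers, cfg)
  feature_raster(grid, matrix(v, grid$n_rows, grid$n_cols), name = name,
                 units = units)
}
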