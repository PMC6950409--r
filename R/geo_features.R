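#' Buffer radius ladder
#'
#' The ordered set of circular-buffer radii over which land-use and
#' greenness predictors are computed. The default spans 250-5000 m and
#' includes every intermediate radius a reported buffer predictor might
#' use (e.g. 1500, 1750, 4250, 4750 m).
#'
#' @param radii Strictly increasing positive radii in meters.
#' @return Numeric vector of class `buffer_ladder`.
#' @export
buffer_ladder <- function(radii = c(250, 500, 750, 1000, 1250, 1500, 1750,
                                    2000, 2500, 3000, 4000, 4250, 4750, 5000)) {
  radii <- as.numeric(radii)
  if (length(radii) == 0 || any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("buffer radii must be positive and strictly increasing", call. = FALSE)
  }
  structure(radii, class = "buffer_ladder")
}

#' Circular focal kernel as cell offsets
#'
#' Enumerates the integer cell offsets `(di, dj)` whose cell-center
#' distance `sqrt(di^2 + dj^2) * cell_size` is at most `radius`
#' (center-in-circle membership, the convention of GIS focal-statistics
#' circles). The kernel always contains `(0, 0)` and is symmetric under
#' 90-degree rotation and reflection.
#'
#' @param radius Buffer radius in meters.
#' @param cell_size Cell size in meters.
#' @return Integer matrix with columns `di`, `dj`, one row per offset.
#' @examples
#' nrow(circular_kernel(50, 50))  # 5: center plus 4-neighbours
#' @export
circular_kernel <- function(radius, cell_size) {
  stopifnot(radius > 0, cell_size > 0)
  m <- floor(radius / cell_size)
  g <- expand.grid(di = -m:m, dj = -m:m)  # di varies fastest (column-major)
  keep <- (g$di^2 + g$dj^2) * cell_size^2 <= radius^2
  out <- as.matrix(g[keep, , drop = FALSE])
  dimnames(out) <- list(NULL, c("di", "dj"))
  storage.mode(out) <- "integer"
  out
}

#' Circular-buffer focal statistic over a raster
#'
#' Computes, for every cell, a statistic of the raster values whose cell
#' centers fall within `radius` of that cell's center. Edge cells use
#' in-grid kernel members only (no padding); `NA` cells are skipped and
#' an all-missing neighborhood yields `NA`.
#'
#' @param raster A [feature_raster()] (continuous layer or 0/1 class mask).
#' @param radius Buffer radius in meters.
#' @param stat `"sum"` or `"mean"`.
#' @param name Output layer name; default `<name>_<radius>m`.
#' @return A [feature_raster()] on the same grid.
#' @export
focal_stat <- function(raster, radius, stat = c("sum", "mean"), name = NULL) {
  stat <- match.arg(stat)
  kern <- circular_kernel(radius, raster$grid$cell_size)
  vals <- focal_apply_cpp(raster$values, kern, if (stat == "mean") 1L else 0L)
  if (is.null(name)) name <- sprintf("%s_%gm", raster$name, radius)
  feature_raster(raster$grid, vals, name = name, units = raster$units)
}

#' Focal statistic at point locations
#'
#' Same kernel and edge semantics as [focal_stat()], evaluated only at
#' the cells containing the supplied coordinates. Equivalent to (and
#' tested against) computing the full focal surface and extracting.
#'
#' @inheritParams focal_stat
#' @param coords A data.frame with columns `x`, `y` in meters.
#' @return Numeric vector, one value per coordinate.
#' @export
focal_at_points <- function(raster, coords, radius, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  idx <- cell_index(raster$grid, coords$x, coords$y)
  if (anyNA(idx$i)) {
    stop("coordinates outside grid bounds in focal_at_points", call. = FALSE)
  }
  kern <- circular_kernel(radius, raster$grid$cell_size)
  focal_points_cpp(raster$values, kern, idx$i, idx$j,
                   if (stat == "mean") 1L else 0L)
}

# ---- vector features (points / polylines in WKT) -------------------------

#' Vector feature layers
#'
#' A vector feature layer is a data.frame with columns `layer` (name),
#' and `wkt` (a `POINT (x y)` or `LINESTRING (x1 y1, x2 y2, ...)` WKT
#' string in planar meters). These cover the point/line inputs of a LUR
#' study: roads, railways, airports, quarry sites.
#'
#' @param layer Character vector of layer names.
#' @param wkt Character vector of WKT geometries.
#' @return A data.frame of class `vector_features`.
#' @export
vector_features <- function(layer, wkt) {
  df <- data.frame(layer = layer, wkt = wkt, stringsAsFactors = FALSE)
  class(df) <- c("vector_features", "data.frame")
  df
}

parse_wkt <- function(s) {
  s <- trimws(s)
  if (grepl("^POINT", s)) {
    nums <- as.numeric(strsplit(trimws(sub("^POINT\\s*\\(", "", sub("\\)$", "", s))),
                                "\\s+")[[1]])
    list(type = "POINT", coords = matrix(nums, ncol = 2, byrow = TRUE))
  } else if (grepl("^LINESTRING", s)) {
    body <- sub("^LINESTRING\\s*\\(", "", sub("\\)$", "", s))
    pts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
    coords <- t(vapply(pts, function(p) as.numeric(p[nzchar(p)]), numeric(2)))
    list(type = "LINESTRING", coords = coords)
  } else {
    stop("unsupported WKT geometry: ", substr(s, 1, 20), call. = FALSE)
  }
}

# distance from points (qx, qy) to one segment (x1,y1)-(x2,y2), vectorised
.dist_to_segment <- function(qx, qy, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((qx - x1)^2 + (qy - y1)^2))
  t <- pmin(1, pmax(0, ((qx - x1) * dx + (qy - y1) * dy) / len2))
  sqrt((qx - (x1 + t * dx))^2 + (qy - (y1 + t * dy))^2)
}

#' Euclidean distance to the nearest feature
#'
#' Point-to-point distance for `POINT` features; point-to-segment for
#' `LINESTRING` features (distance to the nearest segment of the line).
#'
#' @param features A [vector_features()] data.frame (one or more rows).
#' @param query A data.frame with columns `x`, `y` in meters.
#' @return Numeric vector of distances (meters), one per query point.
#' @export
nearest_distance <- function(features, query) {
  if (NROW(features) == 0) stop("empty feature set", call. = FALSE)
  best <- rep(Inf, NROW(query))
  for (w in features$wkt) {
    geom <- parse_wkt(w)
    cc <- geom$coords
    if (geom$type == "POINT") {
      d <- sqrt((query$x - cc[1, 1])^2 + (query$y - cc[1, 2])^2)
      best <- pmin(best, d)
    } else {
      for (s in seq_len(nrow(cc) - 1)) {
        d <- .dist_to_segment(query$x, query$y,
                              cc[s, 1], cc[s, 2], cc[s + 1, 1], cc[s + 1, 2])
        best <- pmin(best, d)
      }
    }
  }
  best
}

#' Nearest-distance raster for a feature layer
#'
#' @param features A [vector_features()] subset (single layer).
#' @param grid A [grid_spec()].
#' @param name Output layer name.
#' @return A [feature_raster()] of distances in meters.
#' @export
distance_raster <- function(features, grid, name = "nearest") {
  centers <- cell_center(grid,
                         i = rep(seq_len(grid$n_rows), times = grid$n_cols),
                         j = rep(seq_len(grid$n_cols), each = grid$n_rows))
  d <- nearest_distance(features, centers)
  feature_raster(grid, matrix(d, grid$n_rows, grid$n_cols), name = name,
                 units = "m")
}

# ---- feature stack -------------------------------------------------------

# hectares covered by one cell
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

#' Build the full buffer-predictor raster stack
#'
#' Produces one raster per (land-use class x buffer radius) — summed
#' class area in hectares within the circular buffer — one per
#' (NDVI x radius) — mean NDVI within the buffer — and one
#' nearest-distance raster per vector layer. Names follow the
#' `<Layer>_<radius>m` / `<Layer>_nearest` convention.
#'
#' @param landuse A land-use scene as returned by [generate_landuse()]:
#'   list with `raster` (class-coded [feature_raster()]) and `classes`
#'   (named integer codes).
#' @param ndvi A single NDVI [feature_raster()] (e.g. a period composite),
#'   or `NULL` to skip.
#' @param vectors A [vector_features()] data.frame, or `NULL`.
#' @param ladder A [buffer_ladder()].
#' @return Named list of [feature_raster()] objects.
#' @export
build_feature_stack <- function(landuse, ndvi = NULL, vectors = NULL,
                                ladder = buffer_ladder()) {
  grid <- landuse$raster$grid
  if (!is.null(ndvi) && !grid_equal(ndvi$grid, grid)) {
    stop("NDVI raster grid does not match land-use grid", call. = FALSE)
  }
  out <- list()
  area_ha <- cell_area_ha(grid)
  for (cls in names(landuse$classes)) {
    mask <- feature_raster(grid,
                           (landuse$raster$values == landuse$classes[[cls]]) * 1,
                           name = cls, units = "ha")
    for (r in ladder) {
      fr <- focal_stat(mask, r, stat = "sum")
      fr$values <- fr$values * area_ha
      out[[fr$name]] <- fr
    }
  }
  if (!is.null(ndvi)) {
    for (r in ladder) {
      nm <- sprintf("NDVI_%gm", r)
      fr <- focal_stat(ndvi, r, stat = "mean", name = nm)
      fr$units <- "index"
      out[[nm]] <- fr
    }
  }
  if (!is.null(vectors) && NROW(vectors) > 0) {
    for (lay in unique(vectors$layer)) {
      nm <- sprintf("%s_nearest", lay)
      out[[nm]] <- distance_raster(vectors[vectors$layer == lay, , drop = FALSE],
                                   grid, name = nm)
    }
  }
  out
}

#' Parse a buffer-predictor name
#'
#' Splits names of the form `<Layer>_<radius>m` (or `<Layer>_nearest`)
#' back into their components.
#'
#' @param name Character vector of layer names.
#' @return data.frame with columns `layer` and `radius` (NA for
#'   non-buffer names).
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([0-9.]+)m$", name))
  layer <- vapply(seq_along(name), function(k) {
    if (length(m[[k]]) == 3) m[[k]][2] else sub("_nearest$", "", name[k])
  }, character(1))
  radius <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[3]) else NA_real_,
                   numeric(1))
  data.frame(layer = layer, radius = radius, name = name,
             stringsAsFactors = FALSE)
}
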