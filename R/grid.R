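#' Planar raster grid geometry
#'
#' A `grid_spec` describes a regular planar grid in projected meters:
#' an origin (lower-left corner), a square cell size, and the number of
#' rows and columns. Rows run south-to-north (row 1 is the bottom row),
#' columns west-to-east; cell `(i, j)` has its center at
#' `origin + (index - 0.5) * cell_size`.
#'
#' @param origin_x,origin_y Planar coordinates of the grid's lower-left
#'   corner, in meters.
#' @param cell_size Cell edge length in meters (default 50, a typical
#'   exposure-surface resolution).
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, 50, 200, 200)  # 10 x 10 km study area
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 50,
                      n_rows = 200, n_cols = 200) {
  stopifnot(is.numeric(cell_size), cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g), extent %g x %g km\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Cell center coordinates
#'
#' @param grid A [grid_spec()].
#' @param i,j Row and column indices (1-based, vectorised).
#' @return A data.frame with columns `x`, `y` (meters).
#' @export
cell_center <- function(grid, i, j) {
  data.frame(x = grid$origin_x + (j - 0.5) * grid$cell_size,
             y = grid$origin_y + (i - 0.5) * grid$cell_size)
}

#' Locate coordinates on the grid
#'
#' Maps planar coordinates to 1-based cell indices using half-open cell
#' intervals `[edge, next_edge)`: a point lying exactly on a shared cell
#' edge belongs to the cell on its east/north side.
#'
#' @inheritParams cell_center
#' @param x,y Planar coordinates in meters (vectorised).
#' @return A data.frame with integer columns `i` (row) and `j` (column);
#'   `NA` for coordinates outside the grid.
#' @export
cell_index <- function(grid, x, y) {
  j <- floor((x - grid$origin_x) / grid$cell_size) + 1
  i <- floor((y - grid$origin_y) / grid$cell_size) + 1
  bad <- i < 1 | i > grid$n_rows | j < 1 | j > grid$n_cols
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Single-band raster tied to a grid
#'
#' Lightweight container pairing a numeric matrix (`n_rows` x `n_cols`)
#' with its [grid_spec()] geometry, a layer name, and a unit label.
#' Layer names follow the machine-parseable `<layer>_<radius>m`
#' convention used for buffer predictors (e.g. `"Residential_4250m"`).
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`.
#' @param name Layer name.
#' @param units Unit label (e.g. `"ha"`, `"index"`, `"m"`, `"ug/m3"`).
#' @return An object of class `feature_raster`.
#' @export
feature_raster <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop(sprintf("raster '%s': values are %d x %d but grid is %d x %d",
                 name, nrow(values), ncol(values), grid$n_rows, grid$n_cols),
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, name = name, units = units, values = values),
            class = "feature_raster")
}

#' @export
print.feature_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<feature_raster> '%s' [%s] %d x %d; range [%g, %g]%s\n",
              x$name, x$units, nrow(v), ncol(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              if (anyNA(v)) sprintf(", %d NA cells", sum(is.na(v))) else ""))
  invisible(x)
}

#' @export
as.matrix.feature_raster <- function(x, ...) x$values

#' Extract raster values at coordinates
#'
#' Returns the value of the cell containing each coordinate (no
#' interpolation), under the same half-open edge convention as
#' [cell_index()].
#'
#' @param raster A [feature_raster()].
#' @param coords A data.frame with columns `x`, `y` (meters) and
#'   optionally an id column used in error messages.
#' @param id Name of the id column in `coords` (default uses row number).
#' @return Numeric vector of cell values.
#' @export
extract_at <- function(raster, coords, id = NULL) {
  idx <- cell_index(raster$grid, coords$x, coords$y)
  if (anyNA(idx$i)) {
    who <- which(is.na(idx$i))
    labels <- if (!is.null(id) && id %in% names(coords)) {
      coords[[id]][who]
    } else who
    stop(sprintf("coordinates outside grid bounds for: %s",
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  raster$values[cbind(idx$i, idx$j)]
}
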