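# Plain-text persistence: rasters as CSV matrices with a JSON geometry
# sidecar, vector features and station tables as CSV, designs as CSV plus
# a JSON candidate-metadata sidecar, and selection traces as JSON lines.

#' Write / read a raster as CSV with a JSON sidecar
#'
#' The cell values are stored as a headerless CSV matrix (row 1 = top
#' row of the map, i.e. the highest `y`); the grid geometry, layer name
#' and units go to `<path>.json`.
#'
#' @param raster A [feature_raster()].
#' @param path Output CSV path (sidecar written next to it).
#' @return `path`, invisibly (`write_raster`); a [feature_raster()]
#'   (`read_raster`).
#' @export
write_raster <- function(raster, path) {
  g <- raster$grid
  # flip so the file reads like a map (north up)
  utils::write.table(raster$values[rev(seq_len(g$n_rows)), , drop = FALSE],
                     path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(origin_x = g$origin_x, origin_y = g$origin_y,
               cell_size = g$cell_size, n_rows = g$n_rows, n_cols = g$n_cols,
               name = raster$name, units = raster$units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  grid <- grid_spec(meta$origin_x, meta$origin_y, meta$cell_size,
                    meta$n_rows, meta$n_cols)
  feature_raster(grid, m[rev(seq_len(grid$n_rows)), , drop = FALSE],
                 name = meta$name, units = meta$units)
}

#' Write / read a design matrix as CSV with candidate metadata
#'
#' The observation table goes to `path`; the candidate-variable table
#' (names, classes, radii, direction priors) to `<path>.json`.
#'
#' @param design A `lur_design`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_design`); a `lur_design`
#'   (`read_design`).
#' @export
write_design <- function(design, path) {
  write.csv(design$data, path, row.names = FALSE)
  jsonlite::write_json(design$candidates, paste0(path, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  data <- read.csv(path, check.names = FALSE)
  cand <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cand$radius <- as.numeric(cand$radius)
  structure(list(data = data, candidates = cand, response = "pm25"),
            class = "lur_design")
}

#' Write a selection trace as JSON lines
#'
#' @param model A `lur_model`.
#' @param path Output path (one JSON object per decision).
#' @return `path`, invisibly.
#' @export
write_trace <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(model$trace))) {
    writeLines(jsonlite::toJSON(as.list(model$trace[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
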