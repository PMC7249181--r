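#' A minimal planar raster grid
#'
#' Local planar coordinates in meters. Values are stored as an
#' `n_rows x n_cols` matrix with row 1 at the top of the map (the ESRI ASCII
#' grid convention); the origin is the lower-left corner.
#'
#' @param values numeric matrix.
#' @param origin_x,origin_y lower-left corner coordinates, m.
#' @param cell_size cell edge, m, `> 0`.
#' @param nodata value marking missing cells.
#' @return an object of class `"raster_grid"`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = 0, cell_size = 10,
                        nodata = -9999) {
  values <- as.matrix(values)
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(
    values = values, origin_x = origin_x, origin_y = origin_y,
    cell_size = cell_size, nodata = nodata,
    n_rows = nrow(values), n_cols = ncol(values)
  ), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata & !is.na(x$values)]
  cat(sprintf(
    "raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y
  ))
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

# cell-center coordinates of every cell, in matrix order
grid_coords <- function(g) {
  col <- rep(seq_len(g$n_cols), each = g$n_rows)
  row <- rep(seq_len(g$n_rows), g$n_cols)
  list(
    x = g$origin_x + (col - 0.5) * g$cell_size,
    y = g$origin_y + (g$n_rows - row + 0.5) * g$cell_size,
    row = row, col = col
  )
}

# nearest-cell lookup; returns NA outside the grid extent
cell_at <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1L
  row <- g$n_rows - floor((y - g$origin_y) / g$cell_size)
  ok <- col >= 1 & col <= g$n_cols & row >= 1 & row <= g$n_rows
  val <- rep(NA_real_, length(x))
  val[ok] <- g$values[cbind(row[ok], col[ok])]
  val
}

check_aligned <- function(a, b) {
  same <- a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
  if (!same) stop("raster grids are not aligned")
  invisible(TRUE)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, top row first.
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @return `read_ascii_grid` returns a [raster_grid()].
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin_x),
    sprintf("yllcorner %.6f", grid$origin_y),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %g", grid$nodata)
  ), con)
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  for (r in seq_len(grid$n_rows)) {
    writeLines(paste(formatC(vals[r, ], format = "g", digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vals[vals == val[["nodata_value"]]] <- NA
  raster_grid(vals,
    origin_x = val[["xllcorner"]], origin_y = val[["yllcorner"]],
    cell_size = val[["cellsize"]], nodata = val[["nodata_value"]]
  )
}
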