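#' Planar analysis grid
#'
#' A regular grid of square cells in a planar (projected, metre-based)
#' coordinate system. Cell centres sit at `origin + (index - 0.5) * cell_size`;
#' row 1 is the southernmost row. All rasters in the package share this
#' layout.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param cell_size cell edge length in metres (default 100, the working
#'   resolution of the distance-to-edge rasters).
#' @param origin numeric length-2, lower-left corner (x, y) in metres.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 100, origin = c(0, 0)) {
  if (!is_count(n_rows) || n_rows < 1) stopf("n_rows must be a positive integer")
  if (!is_count(n_cols) || n_cols < 1) stopf("n_cols must be a positive integer")
  if (!is.numeric(cell_size) || cell_size <= 0) stopf("cell_size must be > 0")
  structure(list(origin = as.numeric(origin), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = as.numeric(cell_size)),
            class = "grid_spec")
}

#' Grid covering a rectangular extent
#'
#' @param extent numeric length-2 (width, height) in metres; must be an exact
#'   multiple of `cell_size`.
#' @inheritParams grid_spec
#' @export
grid_from_extent <- function(extent, cell_size = 100, origin = c(0, 0)) {
  if (any(abs(extent / cell_size - round(extent / cell_size)) > 1e-9))
    stopf("extent (%g x %g) is not a multiple of cell_size (%g)",
          extent[1], extent[2], cell_size)
  grid_spec(n_rows = round(extent[2] / cell_size),
            n_cols = round(extent[1] / cell_size),
            cell_size = cell_size, origin = origin)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_extent <- function(grid) {
  c(xmin = grid$origin[1], ymin = grid$origin[2],
    xmax = grid$origin[1] + grid$n_cols * grid$cell_size,
    ymax = grid$origin[2] + grid$n_rows * grid$cell_size)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with `x` (length n_cols) and `y` (length n_rows).
#' @export
cell_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Locate points on the grid (nearest-cell rule)
#'
#' Maps point coordinates to (row, col) cell indices. Points on the top or
#' right boundary of the extent belong to the last cell; points outside the
#' extent raise an error naming the offending ids.
#'
#' @param grid a [grid_spec()].
#' @param x,y point coordinates in metres.
#' @param ids optional point identifiers used in error messages.
#' @return data.frame with columns `row`, `col`.
#' @export
point_cell <- function(grid, x, y, ids = seq_along(x)) {
  ext <- grid_extent(grid)
  bad <- x < ext["xmin"] - 1e-9 | x > ext["xmax"] + 1e-9 |
         y < ext["ymin"] - 1e-9 | y > ext["ymax"] + 1e-9
  if (any(bad))
    stopf("points outside the grid extent: %s",
          paste(utils::head(ids[bad], 5), collapse = ", "))
  col <- pmin(pmax(floor((x - grid$origin[1]) / grid$cell_size) + 1, 1), grid$n_cols)
  row <- pmin(pmax(floor((y - grid$origin[2]) / grid$cell_size) + 1, 1), grid$n_rows)
  data.frame(row = as.integer(row), col = as.integer(col))
}

new_raster <- function(values, grid, name = "") {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  structure(list(values = values, grid = grid, name = name),
            class = "cr_raster")
}

#' @export
print.cr_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("cr_raster '%s': %d x %d, range [%g, %g]\n", x$name,
              x$grid$n_rows, x$grid$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`.asc`), readable by standard GIS
#' software. Row order in the file is north to south, as the format requires.
#'
#' @param raster a raster object (as produced by e.g. [signed_distance()]).
#' @param path output file path.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  v <- raster$values
  v[!is.finite(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.10g", g$origin[1]),
               sprintf("yllcorner %.10g", g$origin[2]),
               sprintf("cellsize %.10g", g$cell_size),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(g$n_rows)))
    writeLines(paste(format(v[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @return a raster object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  g <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                 c(hdr$xllcorner, hdr$yllcorner))
  new_raster(m, g, name = tools::file_path_sans_ext(basename(path)))
}
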