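#' The twelve land-use classes and their acronyms
#'
#' Canonical table of the major land-use classes used as distance-to-edge
#' predictors: class name, acronym, and the state-wide coverage fraction used
#' as the default target in the synthetic landscape generator. Row order is
#' the canonical variable order used throughout the package.
#'
#' @return data.frame with columns `name`, `acronym`, `coverage`.
#' @export
delv_classes <- function() {
  data.frame(
    name = c("Bushlands", "Fields", "Forests_forestry", "Flowing_watercourses",
             "Green_areas_settlements", "Grass_forbs", "Ruderal_areas",
             "Shrublands", "Special_biotas", "Settlements_structures",
             "Still_watercourses", "Wetlands"),
    acronym = c("B", "F", "FF", "FW", "GS", "GF", "RA", "S", "SB", "SS",
                "SW", "W"),
    coverage = c(0.0079, 0.3511, 0.3551, 0.0039, 0.0166, 0.1637, 0.0026,
                 0.0035, 0.0087, 0.0573, 0.0221, 0.0073),
    stringsAsFactors = FALSE
  )
}

# Cells whose closed square is touched by a segment (separating-axis test).
# Returns a two-column (row, col) index matrix, possibly empty.
segment_cells <- function(grid, x1, y1, x2, y2, tol = 1e-9) {
  h <- grid$cell_size
  ctr <- cell_centers(grid)
  cols <- which(ctr$x >= min(x1, x2) - h / 2 - tol &
                ctr$x <= max(x1, x2) + h / 2 + tol)
  rows <- which(ctr$y >= min(y1, y2) - h / 2 - tol &
                ctr$y <= max(y1, y2) + h / 2 + tol)
  if (!length(cols) || !length(rows)) return(NULL)
  nx <- -(y2 - y1); ny <- x2 - x1
  cseg <- nx * x1 + ny * y1
  r <- (abs(nx) + abs(ny)) * h / 2
  cx <- rep(ctr$x[cols], each = length(rows))
  cy <- rep(ctr$y[rows], times = length(cols))
  hit <- abs(nx * cx + ny * cy - cseg) <= r + tol * (abs(nx) + abs(ny) + 1)
  if (!any(hit)) return(NULL)
  cbind(rep(rows, times = length(cols))[hit],
        rep(cols, each = length(rows))[hit])
}

# Cells whose centre lies on the segment (within 1e-6 m).
centers_on_segment <- function(grid, x1, y1, x2, y2, tol = 1e-6) {
  ctr <- cell_centers(grid)
  cols <- which(ctr$x >= min(x1, x2) - tol & ctr$x <= max(x1, x2) + tol)
  rows <- which(ctr$y >= min(y1, y2) - tol & ctr$y <= max(y1, y2) + tol)
  if (!length(cols) || !length(rows)) return(NULL)
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(NULL)
  cx <- rep(ctr$x[cols], each = length(rows))
  cy <- rep(ctr$y[rows], times = length(cols))
  t <- pmin(pmax(((cx - x1) * dx + (cy - y1) * dy) / len2, 0), 1)
  d2 <- (x1 + t * dx - cx)^2 + (y1 + t * dy - cy)^2
  hit <- d2 < tol * tol
  if (!any(hit)) return(NULL)
  cbind(rep(rows, times = length(cols))[hit],
        rep(cols, each = length(rows))[hit])
}

layer_segments <- function(layer) {
  do.call(rbind, lapply(layer_rings(layer), function(ring) {
    n <- nrow(ring) - 1L
    cbind(ring[seq_len(n), 1], ring[seq_len(n), 2],
          ring[seq_len(n) + 1L, 1], ring[seq_len(n) + 1L, 2])
  }))
}

#' Rasterize class boundaries to an edge-cell mask
#'
#' A cell is an edge cell iff the boundary polyline of the class polygons
#' intersects the cell's square. A boundary segment running exactly along
#' the line between two cells belongs to the cell on the polygon's interior
#' side (the segment is nudged one micrometre inwards before the test), so a
#' polygon tracing one cell's outline marks exactly that cell. Rings are
#' assumed to follow the usual orientation convention (exteriors
#' counter-clockwise, holes clockwise), which puts the interior on the left
#' of each directed segment.
#'
#' @param layer a [land_use_layer()] in the grid's planar coordinate system.
#' @param grid a [grid_spec()].
#' @return logical matrix (`n_rows` x `n_cols`).
#' @export
rasterize_edges <- function(layer, grid) {
  if (!length(layer$polygons)) stopf("no features for class '%s'", layer$class)
  segs <- layer_segments(layer)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  eps <- 1e-6
  hits <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    dx <- segs[s, 3] - segs[s, 1]; dy <- segs[s, 4] - segs[s, 2]
    len <- sqrt(dx^2 + dy^2)
    if (len <= 2 * eps) next
    nx <- -dy / len * eps; ny <- dx / len * eps   # left normal, inward
    ux <- dx / len * eps; uy <- dy / len * eps    # longitudinal shrink
    hits[[s]] <- segment_cells(grid,
                               segs[s, 1] + nx + ux, segs[s, 2] + ny + uy,
                               segs[s, 3] + nx - ux, segs[s, 4] + ny - uy,
                               tol = 0)
  }
  idx <- do.call(rbind, hits)
  if (!is.null(idx) && nrow(idx)) mask[idx] <- TRUE
  mask
}

#' Cells whose centre lies inside a class
#'
#' Even-odd scanline test against all rings of the layer; cell centres that
#' fall exactly on a polygon boundary count as inside (a deterministic tie
#' rule; such cells are edge cells with distance 0 anyway).
#'
#' @inheritParams rasterize_edges
#' @return logical matrix.
#' @export
inside_mask <- function(layer, grid) {
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!length(layer$polygons)) return(mask)
  segs <- layer_segments(layer)
  ctr <- cell_centers(grid)
  keep <- segs[, 2] != segs[, 4]   # horizontals never cross a scanline
  for (i in seq_len(grid$n_rows)) {
    y <- ctr$y[i]
    cr <- keep & ((segs[, 2] > y) != (segs[, 4] > y))
    if (!any(cr)) next
    xc <- segs[cr, 1] + (y - segs[cr, 2]) * (segs[cr, 3] - segs[cr, 1]) /
      (segs[cr, 4] - segs[cr, 2])
    n_left <- rowSums(outer(ctr$x, xc, ">"))
    mask[i, ] <- n_left %% 2L == 1L
  }
  # centres exactly on a boundary count as inside
  hits <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs)))
    hits[[s]] <- centers_on_segment(grid, segs[s, 1], segs[s, 2],
                                    segs[s, 3], segs[s, 4])
  idx <- do.call(rbind, hits)
  if (!is.null(idx) && nrow(idx)) mask[idx] <- TRUE
  mask
}

#' Signed Euclidean distance-to-edge raster
#'
#' Distance (metres, centre to centre on the rasterized edge set) from every
#' cell to the nearest edge cell of a class; negative inside the class,
#' positive outside, zero on edge cells.
#'
#' @param edge_mask logical matrix from [rasterize_edges()]; must contain at
#'   least one edge cell.
#' @param inside logical matrix from [inside_mask()].
#' @param grid a [grid_spec()].
#' @param class_name label stored on the raster.
#' @return a raster object whose values are signed distances in metres.
#' @export
signed_distance <- function(edge_mask, inside, grid, class_name = "") {
  if (!any(edge_mask))
    stopf("no edge cells for class '%s': cannot form distances", class_name)
  d <- edt_cells(edge_mask) * grid$cell_size
  sgn <- matrix(1, grid$n_rows, grid$n_cols)
  sgn[inside] <- -1
  sgn[edge_mask] <- 1            # edge cells are 0, sign irrelevant
  new_raster(d * sgn, grid, name = class_name)
}

#' Build the stack of distance-to-edge rasters
#'
#' Computes one signed distance raster per configured land-use class, all on
#' a shared grid, ordered canonically by acronym (see [delv_classes()])
#' regardless of the input ordering.
#'
#' @param layers list of [land_use_layer()] objects covering exactly the
#'   configured class set.
#' @param grid a [grid_spec()].
#' @param classes class table (default [delv_classes()]).
#' @return an object of class `delv_stack`: list of rasters named by acronym.
#' @export
build_delv_stack <- function(layers, grid, classes = delv_classes()) {
  names(layers) <- vapply(layers, function(l) l$class, "")
  missing <- setdiff(classes$name, names(layers))
  if (length(missing))
    stopf("missing land-use classes: %s", paste(missing, collapse = ", "))
  extra <- setdiff(names(layers), classes$name)
  if (length(extra))
    stopf("unknown land-use classes: %s", paste(extra, collapse = ", "))
  rasters <- lapply(seq_len(nrow(classes)), function(k) {
    layer <- layers[[classes$name[k]]]
    signed_distance(rasterize_edges(layer, grid), inside_mask(layer, grid),
                    grid, class_name = classes$acronym[k])
  })
  names(rasters) <- classes$acronym
  structure(list(grid = grid, rasters = rasters, classes = classes),
            class = "delv_stack")
}

#' @export
print.delv_stack <- function(x, ...) {
  cat(sprintf("delv_stack: %d classes [%s] on %d x %d grid\n",
              length(x$rasters), paste(names(x$rasters), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Sample the distance stack at point locations
#'
#' Nearest-cell rule: each point takes the values of the cell containing it.
#'
#' @param stack a [build_delv_stack()] result.
#' @param points data.frame with columns `x`, `y` and optionally `id`.
#' @return data.frame with one signed-distance column per class acronym.
#' @export
sample_delv <- function(stack, points) {
  ids <- points$id %||% seq_len(nrow(points))
  rc <- point_cell(stack$grid, points$x, points$y, ids = ids)
  idx <- cbind(rc$row, rc$col)
  out <- as.data.frame(lapply(stack$rasters, function(r) r$values[idx]))
  names(out) <- names(stack$rasters)
  out
}

# Full-grid feature matrix (one row per cell, column-major cell order).
delv_features_matrix <- function(stack) {
  m <- vapply(stack$rasters, function(r) as.vector(r$values),
              numeric(stack$grid$n_rows * stack$grid$n_cols))
  colnames(m) <- names(stack$rasters)
  m
}
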