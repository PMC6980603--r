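#' Land-use polygon layer
#'
#' One layer per land-use class, holding polygons in planar (metre)
#' coordinates. Each polygon is a list of rings; each ring a closed two-column
#' coordinate matrix (first vertex repeated last). Ring semantics are even-odd:
#' a point is inside the layer if it is inside an odd number of rings, which
#' makes holes work without explicit nesting.
#'
#' @param class_name land-use class name (e.g. "Fields").
#' @param polygons list of polygons, each a list of closed ring matrices.
#' @return an object of class `land_use_layer`.
#' @export
land_use_layer <- function(class_name, polygons) {
  polygons <- lapply(polygons, function(poly) {
    lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2) stopf("rings must be two-column matrices")
      if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      unname(ring)
    })
  })
  structure(list(class = class_name, polygons = polygons),
            class = "land_use_layer")
}

#' @export
print.land_use_layer <- function(x, ...) {
  cat(sprintf("land_use_layer '%s': %d polygon(s), %d ring(s)\n", x$class,
              length(x$polygons), sum(lengths(x$polygons))))
  invisible(x)
}

layer_rings <- function(layer) unlist(layer$polygons, recursive = FALSE)

ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[-n, 1]; y <- ring[-n, 2]
  x2 <- ring[-1, 1]; y2 <- ring[-1, 2]
  sum(x * y2 - x2 * y) / 2
}

#' Write a land-use layer to GeoJSON
#'
#' One FeatureCollection per class; each polygon becomes a Feature with a
#' `"class"` property.
#'
#' @param layer a [land_use_layer()].
#' @param path output path.
#' @export
write_layer_geojson <- function(layer, path) {
  features <- lapply(layer$polygons, function(poly) {
    coords <- lapply(poly, function(ring)
      lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
    list(type = "Feature",
         properties = list(class = layer$class),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

geojson_geom_polys <- function(geom) {
  to_ring <- function(coords)
    do.call(rbind, lapply(coords, function(pt) as.numeric(unlist(pt))))
  if (geom$type == "Polygon") {
    list(lapply(geom$coordinates, to_ring))
  } else if (geom$type == "MultiPolygon") {
    lapply(geom$coordinates, function(poly) lapply(poly, to_ring))
  } else {
    stopf("unsupported geometry type '%s'", geom$type)
  }
}

#' Read a land-use layer from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of (Multi)Polygons carrying a
#'   `"class"` property.
#' @param class_name override the class name; defaults to the first feature's
#'   property.
#' @export
read_layer_geojson <- function(path, class_name = NULL) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) stopf("not a FeatureCollection")
  polys <- list()
  for (ft in fc$features) {
    if (is.null(class_name)) class_name <- ft$properties$class
    polys <- c(polys, geojson_geom_polys(ft$geometry))
  }
  land_use_layer(class_name %||% "unknown", polys)
}

# Even-odd point-in-rings test; points on a ring edge count as inside.
# x, y vectorised over points.
points_in_rings <- function(rings, x, y, tol = 1e-9) {
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (ring in rings) {
    n <- nrow(ring) - 1L
    x1 <- ring[seq_len(n), 1]; y1 <- ring[seq_len(n), 2]
    x2 <- ring[seq_len(n) + 1L, 1]; y2 <- ring[seq_len(n) + 1L, 2]
    for (k in seq_along(x)) {
      px <- x[k]; py <- y[k]
      # on-segment test
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
      t <- pmin(pmax(t, 0), 1)
      d2 <- (x1 + t * dx - px)^2 + (y1 + t * dy - py)^2
      if (any(d2 < tol * tol)) { on_edge[k] <- TRUE; next }
      # half-open ray casting, ray towards +x
      cross <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      if (sum(cross) %% 2 == 1) inside[k] <- !inside[k]
    }
  }
  inside | on_edge
}
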