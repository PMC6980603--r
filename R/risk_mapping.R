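#' Predict the collision-potential raster
#'
#' Applies a fitted model to every cell of the distance-to-edge stack,
#' producing the per-cell probability of a collision detection. Cells with
#' missing distances propagate NA.
#'
#' @param model a `brt_model` whose variables are a subset of the stack's
#'   class acronyms.
#' @param stack a [build_delv_stack()] result.
#' @return a raster of collision potential in \[0, 1\].
#' @export
predict_cp_raster <- function(model, stack) {
  for (r in stack$rasters)
    if (!same_grid(r$grid, stack$grid)) stopf("grid mismatch within stack")
  miss <- setdiff(model$var_names, names(stack$rasters))
  if (length(miss))
    stopf("stack lacks model variable(s): %s", paste(miss, collapse = ", "))
  feats <- delv_features_matrix(stack)[, model$var_names, drop = FALSE]
  ok <- stats::complete.cases(feats)
  p <- rep(NA_real_, nrow(feats))
  if (any(ok)) p[ok] <- predict(model, feats[ok, , drop = FALSE],
                                type = "response")
  new_raster(matrix(p, stack$grid$n_rows, stack$grid$n_cols),
             stack$grid, name = "collision_potential")
}

#' Relative breeding-pair density raster
#'
#' Per cell, the lower class border of the covering density quadrant divided
#' by the maximum lower border (51 breeding pairs, the lower border of the
#' highest density class). Cells not covered by any quadrant get 0.
#'
#' @param density_map a [generate_density_map()] result (or equivalent).
#' @param grid target [grid_spec()].
#' @return a raster of relative density in \[0, 1\].
#' @export
relative_density <- function(density_map, grid) {
  bpd_max <- max(density_map$lower_borders)
  ctr <- cell_centers(grid)
  qs <- density_map$quadrant_size
  qcol <- floor((ctr$x - density_map$origin[1]) / qs) + 1
  qrow <- floor((ctr$y - density_map$origin[2]) / qs) + 1
  v <- matrix(0, grid$n_rows, grid$n_cols)
  ok_r <- qrow >= 1 & qrow <= density_map$n_qrows
  ok_c <- qcol >= 1 & qcol <= density_map$n_qcols
  for (i in which(ok_r))
    v[i, ok_c] <- density_map$lower_borders[
      density_map$class_index[qrow[i], qcol[ok_c]]] / bpd_max
  new_raster(v, grid, name = "bpd_rel")
}

#' Strike-susceptibility raster
#'
#' Cellwise `SC = CP x BPDrel x 100`, a 0-100 index combining the
#' landscape-driven collision potential with the relative regional density
#' of the species.
#'
#' @param cp collision-potential raster ([predict_cp_raster()]).
#' @param bpdrel relative-density raster ([relative_density()]).
#' @return a raster of strike susceptibility in \[0, 100\].
#' @export
strike_susceptibility <- function(cp, bpdrel) {
  if (!same_grid(cp$grid, bpdrel$grid)) stopf("grid mismatch")
  new_raster(cp$values * bpdrel$values * 100, cp$grid,
             name = "strike_susceptibility")
}

sc_class_labels <- function()
  c("0-20%", "21-40%", "41-60%", "61-80%", "81-100%")

#' Classify strike susceptibility into five zones
#'
#' Bins \[0, 20\], (20, 40\], (40, 60\], (60, 80\], (80, 100\]: half-open at
#' the lower edge except the first, so the bins are exhaustive and disjoint.
#'
#' @param sc strike-susceptibility raster.
#' @return an integer raster of classes 1-5 (NA propagated).
#' @export
classify_sc <- function(sc) {
  v <- sc$values
  cls <- pmin(pmax(ceiling(v / 20), 1), 5)
  new_raster(cls, sc$grid, name = "sc_class")
}

# truncated (not rounded) percentage with 2 decimals
trunc_pct <- function(count, total)
  if (total > 0) trunc(count / total * 1e4) / 1e2 else 0

#' Summarise susceptibility-zone counts
#'
#' From per-class turbine counts: truncated two-decimal percentages per
#' class, the total, and the count and truncated percentage of turbines in
#' zones above 60% susceptibility.
#'
#' @param counts numeric vector of 5 per-class counts.
#' @return list `counts, percent, total, above60_count, above60_percent`.
#' @export
zone_summary <- function(counts) {
  if (length(counts) != 5) stopf("expected 5 class counts")
  total <- sum(counts)
  list(counts = counts,
       percent = vapply(counts, trunc_pct, 0, total = total),
       total = total,
       above60_count = sum(counts[4:5]),
       above60_percent = trunc_pct(sum(counts[4:5]), total))
}

#' Count turbines per status and susceptibility zone
#'
#' @param turbines turbine table with `x`, `y`, `status` (and optionally
#'   `id`); all inside the raster extent.
#' @param class_raster raster of classes 1-5 ([classify_sc()]).
#' @param statuses statuses to tabulate, in output order (default the
#'   statuses present).
#' @return object of class `zone_count_table`: data.frame `status, zone,
#'   count, percent`, with per-status totals and the overall above-60% count
#'   and truncated percentage as attributes.
#' @export
count_turbines_by_class <- function(turbines, class_raster, statuses = NULL) {
  rc <- point_cell(class_raster$grid, turbines$x, turbines$y,
                   ids = turbines$id %||% seq_len(nrow(turbines)))
  cls <- class_raster$values[cbind(rc$row, rc$col)]
  statuses <- statuses %||% unique(turbines$status)
  rows <- list()
  totals <- stats::setNames(numeric(length(statuses)), statuses)
  for (s in statuses) {
    counts <- vapply(1:5, function(k)
      sum(turbines$status == s & cls == k, na.rm = TRUE), 0)
    sm <- zone_summary(counts)
    totals[s] <- sm$total
    rows[[s]] <- data.frame(status = s, zone = sc_class_labels(),
                            count = counts, percent = sm$percent,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  all_counts <- vapply(1:5, function(k) sum(cls[turbines$status %in% statuses] == k,
                                            na.rm = TRUE), 0)
  overall <- zone_summary(all_counts)
  structure(out, class = c("zone_count_table", "data.frame"),
            totals = totals, above60_count = overall$above60_count,
            above60_percent = overall$above60_percent)
}

#' Write a zone-count table as CSV
#'
#' Mirrors the per-status layout plus a totals row per status and the
#' overall above-60% summary.
#'
#' @param zt a [count_turbines_by_class()] result.
#' @param path output path.
#' @export
write_zone_counts <- function(zt, path) {
  totals <- attr(zt, "totals")
  tot_rows <- data.frame(status = names(totals), zone = "total",
                         count = as.numeric(totals), percent = 100,
                         stringsAsFactors = FALSE)
  all <- rbind(as.data.frame(zt), tot_rows,
               data.frame(status = "all", zone = "above-60%",
                          count = attr(zt, "above60_count"),
                          percent = attr(zt, "above60_percent")))
  utils::write.csv(all, path, row.names = FALSE)
  invisible(path)
}

#' Gaussian kernel point-density raster
#'
#' Smoothed point counts per square metre: points are binned to cells and
#' convolved with a discretely normalised Gaussian kernel, so the integral
#' of the surface over the raster equals the number of points whose kernel
#' mass stays inside the extent.
#'
#' @param points data.frame with `x`, `y`.
#' @param bandwidth Gaussian standard deviation in metres (> 0).
#' @param grid a [grid_spec()].
#' @return a density raster (points per square metre).
#' @export
point_density_raster <- function(points, bandwidth, grid) {
  if (bandwidth <= 0) stopf("bandwidth must be > 0")
  if (!nrow(points)) {
    warning("empty point set: returning a zero raster")
    return(new_raster(matrix(0, grid$n_rows, grid$n_cols), grid,
                      name = "density"))
  }
  rc <- point_cell(grid, points$x, points$y)
  counts <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(rc)))
    counts[rc$row[k], rc$col[k]] <- counts[rc$row[k], rc$col[k]] + 1
  h <- grid$cell_size
  m <- max(1L, ceiling(4 * bandwidth / h))
  k1 <- stats::dnorm(seq(-m, m) * h, sd = bandwidth)
  k1 <- k1 / sum(k1)
  conv1 <- function(v) {  # truncated 1-D convolution, same length
    n <- length(v)
    out <- numeric(n)
    for (o in seq(-m, m)) {
      w <- k1[o + m + 1]
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      out[ok] <- out[ok] + w * v[src[ok]]
    }
    out
  }
  sm <- apply(counts, 2, conv1)        # along rows (y)
  sm <- t(apply(sm, 1, conv1))         # along cols (x)
  new_raster(sm / h^2, grid, name = "density")
}
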