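small_stack <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ls <- generate_landscape(landscape_config(extent = c(5000, 5000),
                                                seed = 13))
      val <<- build_delv_stack(ls$layers, ls$grid)
    }
    val
  }
})

test_that("collision-potential rasters are probabilities matching predict", {
  stack <- small_stack()
  m <- cached_model()
  cp <- predict_cp_raster(m, stack)
  v <- cp$values
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  # spot-check cells against pointwise prediction
  withr::with_seed(5, {
    cells <- cbind(sample(50, 20, TRUE), sample(50, 20, TRUE))
  })
  pts <- data.frame(x = (cells[, 2] - 0.5) * 100,
                    y = (cells[, 1] - 0.5) * 100)
  want <- predict(m, sample_delv(stack, pts))
  expect_equal(v[cells], want, tolerance = 1e-12)
  # intercept-only model: uniform raster at prevalence
  X <- as.matrix(cached_ts()[, delv_classes()$acronym])
  m0 <- manual_model(list(), stats::qlogis(0.4), 0.1, X, nt = 0)
  cp0 <- predict_cp_raster(m0, stack)
  expect_true(all(abs(cp0$values - 0.4) < 1e-12))
})

test_that("relative density follows the lower class borders over 51", {
  g <- grid_from_extent(c(10000, 10000))
  top <- generate_density_map(g, 5000, class_probs = c(0, 0, 0, 0, 0, 1),
                              seed = 1)
  expect_true(all(relative_density(top, g)$values == 1))
  bottom <- generate_density_map(g, 5000, class_probs = c(1, 0, 0, 0, 0, 0),
                                 seed = 1)
  expect_true(all(abs(relative_density(bottom, g)$values - 1 / 51) < 1e-12))
  # cells outside the mapped quadrants get zero
  wide <- grid_spec(100, 150, 100)   # extends 5 km east of the map
  r <- relative_density(top, wide)
  expect_true(all(r$values[, 1:100] == 1))
  expect_true(all(r$values[, 101:150] == 0))
})

test_that("strike susceptibility implements CP x BPDrel x 100", {
  g <- grid_spec(2, 2, 100)
  mk <- function(v) collrisk:::new_raster(matrix(v, 2, 2), g)
  expect_equal(strike_susceptibility(mk(1), mk(51 / 51))$values[1, 1], 100)
  expect_equal(strike_susceptibility(mk(0.5), mk(1))$values[1, 1], 50)
  expect_equal(strike_susceptibility(mk(0.2), mk(8 / 51))$values[1, 1],
               0.2 * (8 / 51) * 100, tolerance = 1e-9)
  expect_equal(round(strike_susceptibility(mk(0.2), mk(8 / 51))$values[1, 1],
                     3), 3.137)
  g2 <- grid_spec(3, 2, 100)
  expect_error(strike_susceptibility(mk(1),
                                     collrisk:::new_raster(matrix(1, 3, 2), g2)),
               "mismatch")
  # bounds: SC in [0, 100], and 100 only at CP = 1 with the top class
  withr::with_seed(3, {
    cp <- mk(runif(4)); bp <- mk(sample(c(1, 2, 4, 8, 21, 51), 4, TRUE) / 51)
  })
  sc <- strike_susceptibility(cp, bp)$values
  expect_true(all(sc >= 0 & sc <= 100))
})

test_that("susceptibility classes use half-open 20-point bins", {
  g <- grid_spec(1, 8, 100)
  sc <- collrisk:::new_raster(matrix(c(0, 20, 20.5, 40, 60.2, 80, 99, 100),
                                     1, 8), g)
  cls <- classify_sc(sc)$values
  expect_equal(as.vector(cls), c(1, 1, 2, 2, 4, 4, 5, 5))
  # histogram oracle on a random raster
  withr::with_seed(6, v <- matrix(runif(400, 0, 100), 20, 20))
  cls2 <- classify_sc(collrisk:::new_raster(v, grid_spec(20, 20, 100)))$values
  oracle <- cut(v, c(-Inf, 20, 40, 60, 80, Inf), labels = FALSE)
  expect_equal(as.vector(cls2), as.vector(oracle))
})

test_that("rescaling CP against 1/BPDrel leaves the zones unchanged", {
  g <- grid_spec(10, 10, 100)
  withr::with_seed(9, {
    cp <- matrix(runif(100, 0, 0.5), 10, 10)
    bp <- matrix(sample(c(8, 21, 51), 100, TRUE) / 51, 10, 10)
  })
  mk <- function(v) collrisk:::new_raster(v, g)
  c1 <- classify_sc(strike_susceptibility(mk(cp), mk(bp)))
  c2 <- classify_sc(strike_susceptibility(mk(cp * 1.7), mk(bp / 1.7)))
  expect_equal(c1$values, c2$values)
})

test_that("zone counting conserves totals and truncates percentages", {
  g <- grid_spec(1, 5, 100)
  cls <- collrisk:::new_raster(matrix(1:5, 1, 5), g)
  tb <- data.frame(x = c(50, 150, 150, 250, 450), y = rep(50, 5),
                   status = c("approved", "approved", "approved",
                              "proposed", "proposed"))
  zt <- count_turbines_by_class(tb, cls)
  expect_equal(sum(zt$count), nrow(tb))
  expect_equal(unname(attr(zt, "totals")),
               c(3, 2)[match(c("approved", "proposed"),
                             names(attr(zt, "totals")))])
  # all turbines in one class
  one <- data.frame(x = rep(50, 4), y = rep(50, 4), status = "approved")
  z1 <- count_turbines_by_class(one, cls)
  expect_equal(z1$percent[z1$zone == "0-20%"], 100)
  expect_true(all(z1$percent[z1$zone != "0-20%"] == 0))
  # truncation: 1/3 -> 33.33, not 33.34; and 2/3 -> 66.66
  thirds <- data.frame(x = c(50, 150, 150), y = rep(50, 3),
                       status = "approved")
  z3 <- count_turbines_by_class(thirds, cls)
  expect_equal(z3$percent[1:2], c(33.33, 66.66))
  expect_error(count_turbines_by_class(
    data.frame(x = 1000, y = 50, status = "approved", id = "t7"), cls), "t7")
})

test_that("zone summaries recover totals and the above-60% share", {
  s <- zone_summary(c(856, 67, 2, 3, 1))
  expect_equal(s$total, 929)
  expect_equal(s$percent, c(92.14, 7.21, 0.21, 0.32, 0.10))
  expect_equal(s$above60_count, 4)
  s2 <- zone_summary(c(382, 32, 0, 0, 0))
  expect_equal(s2$percent[1:2], c(92.27, 7.72))
})

test_that("kernel density surfaces conserve mass and scale linearly", {
  g <- grid_spec(40, 40, 100)
  p1 <- data.frame(x = 1950, y = 1950)
  d1 <- point_density_raster(p1, bandwidth = 300, g)
  # unimodal with the peak at the point's cell
  expect_equal(which(d1$values == max(d1$values), arr.ind = TRUE)[1, ],
               c(row = 20, col = 20))
  expect_equal(sum(d1$values) * 100^2, 1, tolerance = 0.01)
  # linearity: doubling the points doubles the surface
  d2 <- point_density_raster(rbind(p1, p1), 300, g)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  # mass conservation for many interior points
  withr::with_seed(8, pts <- data.frame(x = runif(200, 1200, 2800),
                                        y = runif(200, 1200, 2800)))
  dm <- point_density_raster(pts, 250, g)
  expect_equal(sum(dm$values) * 100^2 / 200, 1, tolerance = 0.01)
  expect_warning(d0 <- point_density_raster(p1[0, ], 300, g), "empty")
  expect_true(all(d0$values == 0))
})
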