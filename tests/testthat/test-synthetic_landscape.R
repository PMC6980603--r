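test_that("landscape config rejects invalid coverages and extents", {
  expect_error(landscape_config(class_coverages = c(A = 0.7, B = 0.5)),
               "sum")
  expect_error(landscape_config(class_coverages = c(A = -0.1)), "\\[0, 1\\]")
  expect_error(landscape_config(extent = c(1050, 1000)), "multiple")
})

test_that("a single full-coverage class tiles the whole region", {
  cfg <- landscape_config(extent = c(2000, 2000),
                          class_coverages = c(Fields = 1), seed = 2)
  ls <- generate_landscape(cfg)
  expect_true(all(ls$class_matrix == 1))
  expect_equal(unname(ls$realized_coverage), 1)
  m <- inside_mask(ls$layers$Fields, ls$grid)
  expect_true(all(m))
})

test_that("landscapes partition the region and are seed-deterministic", {
  cfg <- landscape_config(extent = c(6000, 6000), seed = 9)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$class_matrix, b$class_matrix)
  expect_true(all(a$class_matrix %in% seq_len(12)))
  # per-class masks partition: each cell claimed exactly once
  counts <- Reduce(`+`, lapply(seq_len(12), function(k)
    (a$class_matrix == k) * 1L))
  expect_true(all(counts == 1L))
})

test_that("default coverages are realised on a 20 km landscape", {
  cfg <- landscape_config(seed = 1)   # 20 km x 20 km defaults
  ls <- generate_landscape(cfg)
  expect_gte(ls$realized_coverage[["Fields"]], 0.28)
  expect_lte(ls$realized_coverage[["Fields"]], 0.42)
  tgt <- cfg$class_coverages / sum(cfg$class_coverages)
  expect_true(all(abs(ls$realized_coverage / tgt - 1) <= 0.2))
})

test_that("turbine generation respects counts, statuses and determinism", {
  g <- grid_from_extent(c(5000, 5000))
  expect_error(generate_turbines(0, g), "empty")
  tb <- generate_turbines(10, g, c(functional = 1, approved = 0,
                                   proposed = 0), seed = 1)
  expect_equal(nrow(tb), 10)
  expect_true(all(tb$status == "functional"))
  tb2 <- generate_turbines(10, g, c(functional = 1, approved = 0,
                                    proposed = 0), seed = 1)
  expect_identical(tb, tb2)
  # status proportions within binomial 99% bounds at n = 1000
  big <- generate_turbines(1000, g, c(functional = 0.5, approved = 0.3,
                                      proposed = 0.2), seed = 4)
  n_f <- sum(big$status == "functional")
  expect_gte(n_f, qbinom(0.005, 1000, 0.5))
  expect_lte(n_f, qbinom(0.995, 1000, 0.5))
  n_a <- sum(big$status == "approved")
  expect_gte(n_a, qbinom(0.005, 1000, 0.3))
  expect_lte(n_a, qbinom(0.995, 1000, 0.3))
  ext <- range(big$x)
  expect_true(ext[1] >= 0 && ext[2] <= 5000)
})

make_small_world <- function(seed = 5) {
  cfg <- landscape_config(extent = c(6000, 6000), seed = seed)
  ls <- generate_landscape(cfg)
  list(ls = ls, stack = build_delv_stack(ls$layers, ls$grid))
}

test_that("collision simulation follows the specified Bernoulli model", {
  w <- make_small_world()
  tb <- generate_turbines(2000, w$ls$grid, seed = 2)
  # no effects, intercept 0: rate near one half
  flat <- simulate_collisions(tb, w$stack, risk_spec(intercept = 0), seed = 3)
  expect_true(all(flat$probability == 0.5))
  expect_lt(abs(mean(flat$outcome) - 0.5), 0.03)
  # deeply negative intercept: no collisions at all
  none <- simulate_collisions(tb, w$stack, risk_spec(intercept = -20),
                              seed = 3)
  expect_true(all(none$outcome == 0))
  # a +3 step beyond 1000 m from flowing watercourses raises the rate there
  step <- risk_spec(intercept = -1, effects = list(
    FW = cbind(c(999.999, 1000.001), c(0, 3))))
  sim <- simulate_collisions(tb, w$stack, step, seed = 4)
  fw <- sample_delv(w$stack, tb)$FW
  expect_gt(mean(sim$outcome[fw > 1000]), mean(sim$outcome[fw <= 1000]))
  # probabilities lie strictly inside (0, 1)
  expect_true(all(sim$probability > 0 & sim$probability < 1))
  # empirical rate converges to the mean probability
  expect_lt(abs(mean(sim$outcome) - mean(sim$probability)), 0.02)
  # a turbine outside the raster extent is reported by id
  bad <- rbind(tb, data.frame(id = 9999, x = 7000, y = 100,
                              status = "functional"))
  expect_error(simulate_collisions(bad, w$stack, step, seed = 1), "9999")
})

test_that("density maps tile the region into valid classes", {
  g <- grid_from_extent(c(10000, 10000))
  expect_error(generate_density_map(g, quadrant_size = 3000), "divide")
  all6 <- generate_density_map(g, 5000, class_probs = c(0, 0, 0, 0, 0, 1),
                               seed = 1)
  expect_true(all(all6$lower_borders[all6$class_index] == 51))
  all1 <- generate_density_map(g, 5000, class_probs = c(1, 0, 0, 0, 0, 0),
                               seed = 1)
  expect_true(all(all1$lower_borders[all1$class_index] == 1))
  mixed <- generate_density_map(g, 2500, seed = 8)
  expect_true(all(mixed$lower_borders[mixed$class_index] %in%
                    c(1, 2, 4, 8, 21, 51)))
  expect_equal(dim(mixed$class_index), c(4, 4))
})

test_that("carcass records reflect outcomes and family structure", {
  w <- make_small_world()
  tb <- generate_turbines(300, w$ls$grid,
                          c(functional = 1, approved = 0, proposed = 0),
                          seed = 6)
  tb <- simulate_collisions(tb, w$stack, default_risk_spec(), seed = 6)
  cc <- generate_carcasses(tb, seed = 6)
  hits <- tb$id[tb$outcome == 1]
  expect_setequal(cc$turbine_id[cc$species == "Buteo buteo"], hits)
  expect_true(all(cc$family[cc$species %in% c("Buteo buteo",
                                              "Milvus milvus")] ==
                    "Accipitridae"))
  expect_false(any(cc$turbine_id[cc$species != "Buteo buteo"] %in% hits))
})
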