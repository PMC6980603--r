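test_that("Bernoulli deviance matches closed forms and a direct loop", {
  expect_equal(bernoulli_deviance(c(0, 1), c(1e-12, 1 - 1e-12)), 0,
               tolerance = 1e-9)
  expect_equal(bernoulli_deviance(c(0, 1, 1, 0), rep(0.5, 4)), -2 * log(0.5))
  withr::with_seed(2, {
    y <- rbinom(50, 1, 0.4); p <- runif(50, 0.01, 0.99)
  })
  loop <- -2 * sum(y * log(p) + (1 - y) * log(1 - p)) / 50
  expect_equal(bernoulli_deviance(y, p), loop)
  expect_warning(bernoulli_deviance(c(0, 1), c(0, 1)), "clamp")
})

test_that("single trees split where the exhaustive scan says", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      X <- matrix(runif(60 * 4, -10, 10), 60, 4)
      r <- rnorm(60) + 2 * (X[, 2] > 1)
      T <- fit_brt_tree(X, r, tc = 1, min_node = 5)
      oracle <- brute_best_split(X, r, min_node = 5)
      expect_equal(unname(T[1, "var"]), oracle$var)
      expect_equal(unname(T[1, "thr"]), oracle$thr)
      expect_equal(unname(T[1, "improve"]), oracle$gain)
    }
  })
  # a perfectly separating binary feature is found exactly
  X <- cbind(a = rep(c(0, 10), each = 20), b = runif(40))
  r <- rep(c(-1, 1), each = 20)
  T <- fit_brt_tree(X, r, tc = 1, min_node = 5)
  expect_equal(unname(T[1, "var"]), 1)
  expect_equal(unname(T[1, "thr"]), 5)
})

test_that("trees respect the split budget and degenerate inputs", {
  X <- matrix(runif(200), 50, 4)
  T <- fit_brt_tree(X, rnorm(50), tc = 3, min_node = 5)
  expect_lte(sum(T[, "var"] > 0), 3)
  # constant residuals: single leaf with zero value
  T0 <- fit_brt_tree(X, rep(0, 50), tc = 3, min_node = 5)
  expect_equal(nrow(T0), 1)
  expect_equal(unname(T0[1, "value"]), 0)
  # constant features: no split possible
  Tc <- fit_brt_tree(matrix(1, 50, 3), rnorm(50), tc = 2, min_node = 5)
  expect_equal(nrow(Tc), 1)
})

test_that("boosting reduces training deviance monotonically without bagging", {
  df <- direct_train(200, 5, function(X) 0.002 * X[, 2])
  m <- brt_boost(df, brt_config(bf = 1, seed = 5), n_trees = 50, lr = 0.1)
  expect_true(all(diff(m$train_dev) <= 1e-12))
  # on separable data the decrease is strict early on
  expect_lt(m$train_dev[50], m$train_dev[1])
})

test_that("boosting is deterministic and rejects one-class input", {
  df <- direct_train(120, 6, function(X) 0.001 * X[, 1])
  a <- brt_boost(df, brt_config(seed = 9), n_trees = 30, lr = 0.05)
  b <- brt_boost(df, brt_config(seed = 9), n_trees = 30, lr = 0.05)
  expect_identical(a$trees, b$trees)
  bad <- df; bad$label <- 1
  expect_error(brt_boost(bad, brt_config(), n_trees = 5), "both classes")
})

test_that("predictions equal intercept-only prevalence and manual traversal", {
  df <- direct_train(80, 7, function(X) 0 * X[, 1])
  m0 <- brt_boost(df, brt_config(seed = 1), n_trees = 0)
  expect_equal(unique(predict(m0, df)), mean(df$label))
  # hand-built two-tree model: traverse by hand
  X <- cbind(A = c(-2, -1, 1, 2), B = c(5, 15, 5, 15))
  t1 <- rbind(c(1, 0, 2, 3, 1, 0, 4),     # split A < 0
              leaf_node(-1, 2), leaf_node(1, 2))
  t2 <- rbind(c(2, 10, 2, 3, 1, 0, 4),    # split B < 10
              leaf_node(0.5, 2), leaf_node(-0.5, 2))
  m <- manual_model(list(t1, t2), intercept = 0.2, lr = 0.1, X = X)
  want <- 0.2 + 0.1 * (c(-1, -1, 1, 1) + c(0.5, -0.5, 0.5, -0.5))
  expect_equal(predict(m, X, type = "link"), want)
  p <- predict(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(m, X[, 1, drop = FALSE]), "B")
})

test_that("stepped selection handles noise, small n, and records CV state", {
  expect_error(brt_step(direct_train(3, 1, function(X) 0 * X[, 1]),
                        brt_config(k_folds = 2)), "fewer rows")
  # pure-noise labels: selected CV deviance stays near the null deviance
  df <- direct_train(200, 8, function(X) rep(0, nrow(X)))
  m <- suppressWarnings(brt_step(df, brt_config(seed = 8, k_folds = 5,
                                                lr_candidates = c(0.01))))
  expect_lt(abs(m$cv$mean_cv_dev - mean(m$cv$fold_null)) /
              mean(m$cv$fold_null), 0.05)
  expect_equal(m$nt, m$cv$nt)
  expect_length(m$trees, m$cv$nt)
})

test_that("the learning-rate scan descends until 1000 trees are reached", {
  ts <- cached_ts()
  m <- brt_step(ts, brt_config(seed = 1))
  expect_gte(m$cv$nt, 1000)
  scan <- m$cv$lr_scan
  expect_true(all(diff(scan$lr) < 0))
  expect_true(all(scan$nt[-nrow(scan)] < 1000))
})

test_that("influence percentages are normalised and rank signal", {
  m <- cached_model()
  infl <- relative_influence(m)
  expect_equal(sum(infl$influence), 100, tolerance = 1e-6)
  expect_true(all(infl$influence >= 0))
  # a lone informative variable among noise dominates
  df <- direct_train(400, 10, function(X) 3 * (X[, 4] > 1000) - 1.5)
  m1 <- brt_boost(df, brt_config(tc = 2, bf = 1, seed = 10, lr = 0.05),
                  n_trees = 100)
  i1 <- relative_influence(m1)
  expect_equal(i1$variable[1], "FW")
  expect_gt(i1$influence[1], 50)
  # variables that are never split carry exactly zero
  X <- cbind(A = rnorm(100), B = rnorm(100))
  t1 <- rbind(c(1, 0, 2, 3, 2, 0, 100), leaf_node(-1), leaf_node(1))
  mm <- manual_model(list(t1), 0, 0.1, X)
  im <- relative_influence(mm)
  expect_equal(im$influence[im$variable == "A"], 100)
  expect_equal(im$influence[im$variable == "B"], 0)
  expect_error(relative_influence(manual_model(list(rbind(leaf_node(1))),
                                               0, 0.1, X)), "no splits")
})

test_that("influence is equivariant under feature-column permutation", {
  df <- direct_train(200, 11, function(X) 0.002 * X[, 3] - 1)
  m1 <- brt_boost(df, brt_config(seed = 3, bf = 1), n_trees = 60, lr = 0.05)
  perm <- c(5:12, 1:4)
  df2 <- df[, c(perm, 13)]
  m2 <- brt_boost(df2, brt_config(seed = 3, bf = 1), n_trees = 60, lr = 0.05)
  i1 <- relative_influence(m1); i2 <- relative_influence(m2)
  expect_equal(setNames(i2$influence, i2$variable)[i1$variable],
               setNames(i1$influence, i1$variable), tolerance = 1e-8)
})

test_that("partial dependence reproduces step functions and flat models", {
  X <- cbind(A = seq(-5, 5, length.out = 50), B = rnorm(50))
  # intercept-only: flat curve at the intercept
  m0 <- manual_model(list(), intercept = 0.7, lr = 0.1, X = X, nt = 0)
  pd0 <- partial_dependence(m0, "A", n_grid = 10)
  expect_true(all(pd0$fit == 0.7))
  # single tree splitting at zero: a two-level step
  t1 <- rbind(c(1, 0, 2, 3, 1, 0, 50), leaf_node(-2), leaf_node(2))
  m1 <- manual_model(list(t1), 0, 0.5, X)
  pd1 <- partial_dependence(m1, "A", n_grid = 21)
  expect_setequal(round(unique(pd1$fit), 9), c(-1, 1))
  expect_true(all(pd1$fit[pd1$distance < 0] == -1))
  expect_true(all(pd1$fit[pd1$distance > 0] == 1))
  expect_true(all(diff(pd1$distance) > 0))
  # row order of the training data is irrelevant
  m2 <- m1; m2$X <- X[sample(50), ]
  expect_equal(partial_dependence(m2, "A", 21)$fit, pd1$fit)
  expect_error(partial_dependence(m1, "Z"), "unknown")
})

test_that("interaction sizes vanish for additive models and are symmetric", {
  X <- cbind(A = runif(60, -1, 1), B = runif(60, -1, 1), C = runif(60))
  tA <- rbind(c(1, 0, 2, 3, 1, 0, 60), leaf_node(-1), leaf_node(1))
  tB <- rbind(c(2, 0.3, 2, 3, 1, 0, 60), leaf_node(2), leaf_node(-2))
  m <- manual_model(list(tA, tB), 0, 0.2, X)
  expect_lt(interaction_size(m, "A", "B", grid_size = 8), 1e-6)
  expect_error(interaction_size(m, "A", "A"), "differ")
  # symmetry on a genuinely interacting fit
  df <- direct_train(200, 12, function(X)
    2 * (X[, 1] > 1000) * (X[, 2] > 1000) - 1)
  mi <- brt_boost(df, brt_config(tc = 4, seed = 12, lr = 0.05),
                  n_trees = 150)
  s_ij <- interaction_size(mi, "B", "F", grid_size = 10)
  s_ji <- interaction_size(mi, "F", "B", grid_size = 10)
  expect_equal(s_ij, s_ji, tolerance = 1e-9)
})

test_that("interacting drivers out-rank noise pairs across seeds", {
  wins <- 0
  for (sd in 1:10) {
    df <- direct_train(250, 100 + sd, function(X)
      2.5 * (X[, 1] > 1000) * (X[, 2] > 1000) - 1.2)
    m <- brt_boost(df, brt_config(tc = 4, seed = sd, lr = 0.05),
                   n_trees = 150)
    s_drv <- interaction_size(m, "B", "F", grid_size = 10)
    noise <- max(interaction_size(m, "GS", "SW", grid_size = 10),
                 interaction_size(m, "RA", "W", grid_size = 10),
                 interaction_size(m, "S", "SB", grid_size = 10))
    if (s_drv > noise) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("simplification drops the weakest predictors and refits", {
  ts <- cached_ts()
  cfg <- brt_config(lr = 0.01, seed = 1)
  m <- brt_step(ts, cfg)
  expect_error(brt_simplify(m, ts, max_drop = 12), "max_drop")
  s0 <- brt_simplify(m, ts, max_drop = 0)
  expect_identical(s0$model$var_names, m$var_names)
  s2 <- brt_simplify(m, ts, max_drop = 2)
  expect_length(s2$model$var_names, 10)
  expect_equal(nrow(s2$drops), 2)
  expect_false(any(s2$drops$dropped %in% s2$model$var_names))
})

test_that("evaluation reports rank AUC, oracle-checked, with thresholds", {
  X <- cbind(A = 1:50, B = rnorm(50))
  m <- manual_model(list(), 0, 0.1, X, nt = 0)
  # perfect ranking
  perfect <- data.frame(A = 1, B = 1, label = c(rep(0, 25), rep(1, 25)))
  expect_equal(auc_rank(perfect$label, seq_len(50)), 1)
  # AUC equals the all-pairs concordance oracle (and pROC agrees)
  withr::with_seed(20, {
    y <- rbinom(50, 1, 0.5); s <- runif(50)
    s[3] <- s[4]   # force a tie
  })
  expect_equal(auc_rank(y, s), brute_auc(y, s))
  if (requireNamespace("pROC", quietly = TRUE))
    expect_equal(auc_rank(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  # labels independent of predictions: AUC near one half
  withr::with_seed(21, {
    y2 <- rbinom(2000, 1, 0.5); s2 <- runif(2000)
  })
  expect_gt(auc_rank(y2, s2), 0.45)
  expect_lt(auc_rank(y2, s2), 0.55)
  # evaluation object sanity on a fitted model
  ts <- cached_ts()
  mm <- cached_model()
  ev <- evaluate_brt(mm, ts)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_true(ev$sensitivity >= 0 && ev$sensitivity <= 1)
  expect_true(ev$one_minus_specificity >= 0 &&
                ev$one_minus_specificity <= 1)
  one <- ts[ts$label == 1, ]
  expect_error(evaluate_brt(mm, one), "both classes")
  # fixed threshold is honoured
  ev2 <- evaluate_brt(mm, ts, threshold = 0.5)
  expect_equal(ev2$threshold, 0.5)
})

test_that("serialized models reload and predict identically", {
  m <- cached_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_brt_model(m, f)
  m2 <- read_brt_model(f)
  ts <- cached_ts()
  expect_equal(predict(m2, ts, type = "link"), predict(m, ts, type = "link"),
               tolerance = 1e-12)
  expect_equal(m2$var_names, m$var_names)
  pd1 <- partial_dependence(m, "GF", 20)
  pd2 <- partial_dependence(m2, "GF", 20)
  expect_equal(pd2$fit, pd1$fit, tolerance = 1e-12)
})
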