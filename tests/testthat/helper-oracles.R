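# Independent oracles and small fixture builders shared across tests.

# axis-aligned rectangle layer
rect_layer <- function(class, xmin, ymin, xmax, ymax) {
  land_use_layer(class, list(list(rbind(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
    c(xmin, ymin)))))
}

# brute-force signed distance: min centre-to-centre distance over all edge
# cells, negated inside (edge cells zero)
brute_signed_distance <- function(edge, inside, grid) {
  ctr <- cell_centers(grid)
  ei <- which(edge, arr.ind = TRUE)
  ex <- ctr$x[ei[, 2]]; ey <- ctr$y[ei[, 1]]
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      d <- sqrt(min((ex - ctr$x[j])^2 + (ey - ctr$y[i])^2))
      s <- if (edge[i, j]) 0 else if (inside[i, j]) -1 else 1
      out[i, j] <- if (edge[i, j]) 0 else s * d
    }
  }
  out
}

# exhaustive best-split scan over every feature and midpoint threshold
brute_best_split <- function(X, r, min_node) {
  n <- nrow(X)
  s_tot <- sum(r); base <- s_tot^2 / n
  best <- list(gain = 0, var = NA, thr = NA)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (k in seq_len(length(vals) - 1)) {
      thr <- (vals[k] + vals[k + 1]) / 2
      left <- X[, j] < thr
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      gain <- sum(r[left])^2 / nl + sum(r[!left])^2 / (n - nl) - base
      if (gain > best$gain + 1e-12) best <- list(gain = gain, var = j, thr = thr)
    }
  }
  best
}

# all-pairs concordance AUC (ties count half)
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  acc <- 0
  for (p in pos) acc <- acc + sum(p > neg) + 0.5 * sum(p == neg)
  acc / (length(pos) * length(neg))
}

# hand-built model from explicit node matrices
manual_model <- function(trees, intercept, lr, X, nt = length(trees)) {
  structure(list(intercept = intercept, lr = lr, nt = nt, trees = trees,
                 var_names = colnames(X), X = X,
                 y = rep(c(0, 1), length.out = nrow(X)),
                 config = brt_config(), seed = 1L, cv = NULL),
            class = "brt_model")
}

# leaf-only tree node row: var thr left right improve value n
leaf_node <- function(value, n = 10) c(0, 0, 0, 0, 0, value, n)

# quick direct training data (no landscape): 12 uniform signed-distance-like
# features, logistic response from a supplied linear predictor function
direct_train <- function(n, seed, eta_fun) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * 12, -1000, 3000), n, 12)
    colnames(X) <- delv_classes()$acronym
    y <- stats::rbinom(n, 1, stats::plogis(eta_fun(X)))
    df <- as.data.frame(X)
    df$label <- y
    df
  })
}

# one small landscape-based training set + stepped model, cached for reuse
cached_ts <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synthetic_training_set(n_per_class = 150,
                                                     seed = 1,
                                                     extent = c(10000, 10000),
                                                     n_turbines = 1200)
    val
  }
})

cached_model <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- brt_boost(cached_ts(), brt_config(lr = 0.01, seed = 1),
                        n_trees = 400)
    val
  }
})
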