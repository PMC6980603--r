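#' Boosted regression tree configuration
#'
#' Calibration parameters of the boosting protocol. Defaults follow common
#' practice for presence/absence distribution models: tree complexity equal
#' to the number of predictors (12), bag fraction 0.5, a descending learning
#' rate scan from 0.05 to 0.0005 aiming for at least 1000 trees, tree number
#' selected by 10-fold cross-validated deviance evaluated every 50 trees.
#'
#' @param tc tree complexity: maximum splits per tree.
#' @param lr fixed learning rate; if `NULL` (default) [brt_step()] scans
#'   `lr_candidates`.
#' @param bf bag fraction in (0, 1]: share of rows subsampled per tree.
#' @param lr_candidates descending learning rates for the scan.
#' @param step_size trees per cross-validation evaluation step.
#' @param max_trees cap on the tree-number scan.
#' @param min_node minimum observations per terminal node.
#' @param k_folds cross-validation folds.
#' @param seed integer seed governing folds and bagging.
#' @return object of class `brt_config`.
#' @export
brt_config <- function(tc = 12, lr = NULL, bf = 0.5,
                       lr_candidates = c(0.05, 0.01, 0.005, 0.001, 0.0005),
                       step_size = 50, max_trees = 10000, min_node = 10,
                       k_folds = 10, seed = 1L) {
  if (tc < 1) stopf("tc must be >= 1")
  if (!is.null(lr) && (lr <= 0 || lr >= 1)) stopf("lr must be in (0, 1)")
  if (bf <= 0 || bf > 1) stopf("bf must be in (0, 1]")
  if (k_folds < 2) stopf("k_folds must be >= 2")
  structure(list(tc = as.integer(tc), lr = lr, bf = bf,
                 lr_candidates = lr_candidates,
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 min_node = as.integer(min_node),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "brt_config")
}

# tie-break ranks: alphabetical by column name, falling back to position
name_ranks <- function(X) {
  if (is.null(colnames(X))) return(seq_len(ncol(X)))
  as.integer(rank(colnames(X), ties.method = "first"))
}

# training-set data.frame -> list(X, y)
ts_xy <- function(data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$X))
    return(list(X = as.matrix(data$X), y = as.numeric(data$y)))
  if (is.null(data$label)) stopf("training data needs a 'label' column")
  feat <- setdiff(names(data), c("turbine_id", "label"))
  list(X = as.matrix(data[, feat, drop = FALSE]), y = as.numeric(data$label))
}

#' Mean Bernoulli deviance
#'
#' `-2 * mean(y log p + (1 - y) log(1 - p))`. Probabilities outside (0, 1)
#' are clamped to `[1e-12, 1 - 1e-12]` with a warning.
#'
#' @param labels 0/1 response.
#' @param probabilities predicted probabilities.
#' @export
bernoulli_deviance <- function(labels, probabilities) {
  if (any(probabilities <= 0 | probabilities >= 1)) {
    warning("probabilities outside (0,1) clamped at 1e-12")
    probabilities <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  }
  -2 * mean(labels * log(probabilities) +
              (1 - labels) * log(1 - probabilities))
}

#' Fit a single regression tree to gradient residuals
#'
#' Greedy best-first recursive binary splitting on squared-error improvement
#' of the residuals, at most `tc` splits, with Newton-step terminal values
#' for Bernoulli loss. Thresholds sit at midpoints of adjacent sorted values;
#' exact improvement ties break towards the alphabetically first variable
#' name, then the lowest threshold, so fits are deterministic and invariant
#' under reordering of the feature columns.
#'
#' @param features numeric matrix or data.frame of predictors.
#' @param residuals current negative gradient (`y - p`).
#' @param hessians per-row curvature (`p (1 - p)`); defaults to 1, which
#'   makes terminal values plain residual means.
#' @param rows logical mask of rows to fit on (the bag); default all.
#' @param tc maximum number of splits.
#' @param min_node minimum rows per terminal node.
#' @return a node matrix with columns
#'   `var, thr, left, right, improve, value, n`.
#' @export
fit_brt_tree <- function(features, residuals, hessians = NULL, rows = NULL,
                         tc = 1, min_node = 10) {
  X <- as.matrix(features)
  if (is.null(hessians)) hessians <- rep(1, nrow(X))
  if (is.null(rows)) rows <- rep(TRUE, nrow(X))
  if (sum(rows) < 2 * min_node && sum(rows) < nrow(X))
    stopf("need at least 2 * min_node sampled rows")
  T <- fit_tree_cpp(X, residuals, hessians, rows, as.integer(tc),
                    as.integer(min_node), name_ranks(X))
  colnames(T) <- c("var", "thr", "left", "right", "improve", "value", "n")
  T
}

#' Fit a boosted regression tree ensemble with a fixed number of trees
#'
#' Forward-stagewise boosting under Bernoulli loss with logit link: the
#' intercept is the empirical log-odds; each iteration subsamples a `bf`
#' fraction of rows without replacement, fits a tree of at most `tc` splits
#' to the current gradient, and appends it scaled by the learning rate.
#'
#' @param data a training-set data.frame (feature columns plus `label`) or a
#'   `list(X, y)`.
#' @param config a [brt_config()].
#' @param n_trees number of boosting iterations.
#' @param lr learning rate; defaults to `config$lr` or 0.005.
#' @param seed seed for bagging; defaults to `config$seed`.
#' @return object of class `brt_model`.
#' @export
brt_boost <- function(data, config = brt_config(), n_trees = 1000,
                      lr = NULL, seed = NULL) {
  xy <- ts_xy(data)
  if (length(unique(xy$y)) < 2)
    stopf("both classes must be present in the training data")
  lr <- lr %||% config$lr %||% 0.005
  seed <- seed %||% config$seed
  icpt <- stats::qlogis(mean(xy$y))
  fit <- boost_cpp(xy$X, xy$y, config$tc, lr, config$bf, config$min_node,
                   as.integer(n_trees), seed_for(seed, 41L), icpt,
                   numeric(0), matrix(numeric(0), 0, ncol(xy$X)),
                   numeric(0), numeric(0), name_ranks(xy$X))
  structure(list(intercept = icpt, lr = lr, nt = as.integer(n_trees),
                 trees = fit$trees, var_names = colnames(xy$X),
                 X = xy$X, y = xy$y, train_dev = fit$train_dev,
                 config = config, seed = seed, cv = NULL),
            class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("brt_model: %d trees (nt = %d), lr = %g, tc = %d, %d predictors\n",
              length(x$trees), x$nt, x$lr, x$config$tc, length(x$var_names)))
  if (!is.null(x$cv))
    cat(sprintf("  CV: %d-fold, mean predicted deviance %.4f at nt = %d\n",
                x$config$k_folds, x$cv$mean_cv_dev, x$cv$nt))
  invisible(x)
}

#' Predict from a boosted regression tree model
#'
#' @param object a `brt_model`.
#' @param newdata data.frame or matrix containing the model's feature
#'   columns (matched by name).
#' @param type `"response"` for probabilities (default), `"link"` for
#'   log-odds.
#' @param n_trees number of trees to use (default the selected `nt`).
#' @param ... unused.
#' @export
predict.brt_model <- function(object, newdata, type = c("response", "link"),
                              n_trees = NULL, ...) {
  type <- match.arg(type)
  n_trees <- n_trees %||% object$nt
  nms <- if (is.data.frame(newdata)) names(newdata) else colnames(newdata)
  miss <- setdiff(object$var_names, nms)
  if (length(miss))
    stopf("missing feature column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$var_names, drop = FALSE])
  storage.mode(X) <- "double"
  f <- predict_link_cpp(object$trees, X, object$intercept, object$lr,
                        as.integer(min(n_trees, length(object$trees))))
  if (type == "link") f else stats::plogis(f)
}

make_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Cross-validated deviance scan at one learning rate: folds are grown in
# chunks until the running arg-min of the mean CV deviance (evaluated on the
# step grid) sits well behind the frontier.
cv_scan <- function(X, y, folds, lr, config, stream) {
  k <- max(folds)
  st <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f)
    list(tr = tr, va = which(folds == f),
         icpt = stats::qlogis(mean(y[tr])), f_tr = numeric(0),
         f_va = numeric(0))
  })
  chunk <- 10L * config$step_size
  total <- 0L
  devmat <- NULL
  repeat {
    add <- min(chunk, config$max_trees - total)
    block <- matrix(NA_real_, add, k)
    for (f in seq_len(k)) {
      s <- st[[f]]
      fit <- boost_cpp(X[s$tr, , drop = FALSE], y[s$tr], config$tc, lr,
                       config$bf, config$min_node, add,
                       seed_for(config$seed, 1000L * stream + 17L * f + total),
                       s$icpt, s$f_tr, X[s$va, , drop = FALSE], s$f_va,
                       y[s$va], name_ranks(X))
      st[[f]]$f_tr <- fit$train_link
      st[[f]]$f_va <- fit$valid_link
      block[, f] <- fit$valid_dev
    }
    devmat <- rbind(devmat, block)
    total <- total + add
    steps <- seq(config$step_size, total, by = config$step_size)
    mean_dev <- rowMeans(devmat)
    best <- steps[which.min(mean_dev[steps])]
    if (total >= config$max_trees || best <= total - 4L * config$step_size)
      break
  }
  null_dev <- vapply(st, function(s)
    bernoulli_deviance(y[s$va], rep(stats::plogis(s$icpt), length(s$va))), 0)
  list(nt = best, fold_dev = devmat[best, ], fold_null = null_dev,
       cv_curve = rowMeans(devmat)[seq(config$step_size, total,
                                       by = config$step_size)],
       steps = seq(config$step_size, total, by = config$step_size))
}

#' Stepped cross-validated selection of learning rate and tree number
#'
#' The stepped boosting protocol: for each candidate learning rate (scanned
#' in descending order), trees are added in cross-validated stages and the
#' tree number minimising the mean k-fold predicted deviance is selected;
#' if the selected number falls short of 1000 trees the next smaller
#' learning rate is tried, so the returned ensemble ideally carries at least
#' 1000 trees. The final model is refit on all rows at the chosen settings
#' and carries the cross-validation records.
#'
#' @inheritParams brt_boost
#' @return a `brt_model` with a `cv` component (folds, per-fold predicted
#'   and null deviances at `nt`, the deviance curve, and the learning-rate
#'   scan table).
#' @export
brt_step <- function(data, config = brt_config()) {
  xy <- ts_xy(data)
  if (length(unique(xy$y)) < 2)
    stopf("both classes must be present in the training data")
  if (nrow(xy$X) < config$k_folds ||
      min(table(xy$y)) < config$k_folds)
    stopf("fewer rows (%d per class) than folds (%d)",
          min(table(xy$y)), config$k_folds)
  folds <- make_folds(xy$y, config$k_folds, seed_for(config$seed, 42L))
  cands <- if (!is.null(config$lr)) config$lr else config$lr_candidates
  scans <- list()
  chosen <- NA_integer_
  for (li in seq_along(cands)) {
    scans[[li]] <- cv_scan(xy$X, xy$y, folds, cands[li], config, li)
    if (scans[[li]]$nt >= 1000 || !is.null(config$lr)) { chosen <- li; break }
  }
  if (is.na(chosen)) {
    chosen <- length(cands)
    warning(sprintf(
      "no learning rate in the scan reached 1000 trees; using lr = %g (nt = %d)",
      cands[chosen], scans[[chosen]]$nt))
  }
  sc <- scans[[chosen]]
  model <- brt_boost(data, config, n_trees = sc$nt, lr = cands[chosen],
                     seed = seed_for(config$seed, 43L))
  fold_cvdev <- 100 * (sc$fold_null - sc$fold_dev) / sc$fold_null
  model$cv <- list(folds = folds, lr = cands[chosen], nt = sc$nt,
                   step_size = config$step_size,
                   fold_dev = sc$fold_dev, fold_null = sc$fold_null,
                   mean_cv_dev = mean(sc$fold_dev),
                   cv_dev_explained = mean(fold_cvdev),
                   cv_dev_explained_se = stats::sd(fold_cvdev) /
                     sqrt(length(fold_cvdev)),
                   cv_curve = sc$cv_curve, steps = sc$steps,
                   lr_scan = data.frame(
                     lr = cands[seq_along(scans)],
                     nt = vapply(scans, function(s) s$nt, 0)))
  model
}

#' Relative influence of each predictor
#'
#' Per-variable sum of squared-error split improvements over the first `nt`
#' trees, normalised to percentages (summing to 100).
#'
#' @param model a `brt_model`.
#' @param n_trees trees to aggregate over (default `nt`).
#' @return data.frame `variable, influence` sorted by decreasing influence.
#' @export
relative_influence <- function(model, n_trees = NULL) {
  n_trees <- n_trees %||% model$nt
  acc <- stats::setNames(numeric(length(model$var_names)), model$var_names)
  for (t in seq_len(min(n_trees, length(model$trees)))) {
    T <- model$trees[[t]]
    int <- T[, 1] > 0
    if (any(int)) {
      s <- tapply(T[int, 5], model$var_names[T[int, 1]], sum)
      acc[names(s)] <- acc[names(s)] + s
    }
  }
  if (sum(acc) <= 0) stopf("model has no splits: influence undefined")
  out <- data.frame(variable = names(acc),
                    influence = 100 * acc / sum(acc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$influence, out$variable), ]
  rownames(out) <- NULL
  out
}

pd_grid <- function(model, variable, n_grid) {
  v <- model$X[, variable]
  g <- unique(as.numeric(stats::quantile(v, probs = seq(0, 1,
                                                        length.out = n_grid))))
  sort(g)
}

#' Partial-dependence curve of one predictor
#'
#' Marginal fitted function on the link scale: at each grid value (equally
#' spaced quantiles of the training values) the mean prediction over all
#' training rows with the variable overwritten by that value.
#'
#' @param model a `brt_model`.
#' @param variable predictor name.
#' @param n_grid grid resolution (default 100).
#' @return data.frame `distance, fit` of class `pdp_curve`.
#' @export
partial_dependence <- function(model, variable, n_grid = 100) {
  j <- match(variable, model$var_names)
  if (is.na(j)) stopf("unknown variable '%s'", variable)
  g <- pd_grid(model, variable, n_grid)
  fit <- pdp1_cpp(model$trees, model$X, model$intercept, model$lr,
                  model$nt, j, g)
  structure(data.frame(distance = g, fit = fit),
            class = c("pdp_curve", "data.frame"), variable = variable)
}

#' Pairwise interaction size of two predictors
#'
#' Builds the two-variable partial-dependence surface on a quantile lattice,
#' fits the best additive (row + column) approximation by least squares, and
#' reports 1000 times the mean squared residual: 0 for perfectly additive
#' pairs, larger when the fitted surface needs an interaction.
#'
#' @param model a `brt_model`.
#' @param var_i,var_j distinct predictor names.
#' @param grid_size lattice resolution per axis (default 20).
#' @return a single non-negative number.
#' @export
interaction_size <- function(model, var_i, var_j, grid_size = 20) {
  if (identical(var_i, var_j)) stopf("var_i and var_j must differ")
  i <- match(var_i, model$var_names); j <- match(var_j, model$var_names)
  if (is.na(i) || is.na(j)) stopf("unknown variable")
  gi <- pd_grid(model, var_i, grid_size)
  gj <- pd_grid(model, var_j, grid_size)
  S <- pdp2_cpp(model$trees, model$X, model$intercept, model$lr, model$nt,
                i, j, gi, gj)
  # least-squares additive fit on a complete balanced lattice
  res <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
  1000 * mean(res^2)
}

#' Drop weakly contributing predictors and refit
#'
#' Model simplification: starting from a fitted model, the currently least
#' influential predictor is removed and the model refit with the stepped
#' cross-validated protocol, up to `max_drop` times; the refit on the
#' retained set is returned together with a drop report.
#'
#' @param model a `brt_model` from [brt_step()] or [brt_boost()].
#' @param data the training data the model was fit on.
#' @param max_drop number of predictors to drop (must be fewer than the
#'   number of predictors).
#' @param config configuration for the refits (default the model's).
#' @return list with `model` (the simplified refit) and `drops` (data.frame
#'   of dropped variable, `nt` and mean CV predicted deviance per stage).
#' @export
brt_simplify <- function(model, data, max_drop = 2, config = NULL) {
  config <- config %||% model$config
  if (max_drop >= length(model$var_names))
    stopf("max_drop (%d) must be smaller than the number of predictors (%d)",
          max_drop, length(model$var_names))
  current <- model
  keep <- model$var_names
  drops <- data.frame(dropped = character(), nt = integer(),
                      cv_dev = numeric())
  if (max_drop == 0) return(list(model = model, drops = drops))
  for (d in seq_len(max_drop)) {
    infl <- relative_influence(current)
    worst <- infl$variable[nrow(infl)]
    keep <- setdiff(keep, worst)
    sub <- data[, c(intersect(c("turbine_id"), names(data)), keep, "label")]
    current <- brt_step(sub, config)
    drops <- rbind(drops, data.frame(
      dropped = worst, nt = current$cv$nt,
      cv_dev = current$cv$mean_cv_dev))
  }
  list(model = current, drops = drops)
}

#' Rank-based area under the ROC curve
#'
#' All-pairs concordance computed from ranks, ties counted half.
#'
#' @param labels 0/1 response.
#' @param scores predicted scores.
#' @export
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on held-out data
#'
#' Computes the rank-statistic AUC, a classification threshold (default the
#' Youden rule maximising sensitivity + specificity - 1), the sensitivity and
#' false-positive rate at that threshold, and - when the model carries
#' cross-validation records - the percent of null deviance explained by the
#' cross-validated predictions with its fold-wise standard error.
#'
#' @param model a `brt_model`.
#' @param newdata held-out training-set data.frame (features plus `label`)
#'   containing both classes.
#' @param threshold fixed classification threshold; overrides the rule.
#' @return object of class `brt_eval`.
#' @export
evaluate_brt <- function(model, newdata, threshold = NULL) {
  y <- newdata$label
  if (length(unique(y)) < 2) stopf("held-out set must contain both classes")
  p <- predict(model, newdata, type = "response")
  auc <- auc_rank(y, p)
  if (is.null(threshold)) {
    cand <- sort(unique(p))
    sens <- vapply(cand, function(t) mean(p[y == 1] >= t), 0)
    spec <- vapply(cand, function(t) mean(p[y == 0] < t), 0)
    threshold <- cand[which.max(sens + spec - 1)]
  }
  sens <- mean(p[y == 1] >= threshold)
  fpr <- mean(p[y == 0] >= threshold)
  cv <- model$cv
  structure(list(auc = auc, sensitivity = sens, one_minus_specificity = fpr,
                 threshold = threshold,
                 cv_dev = if (!is.null(cv)) cv$cv_dev_explained else NA_real_,
                 cv_dev_se = if (!is.null(cv)) cv$cv_dev_explained_se else NA_real_,
                 fold_dev = if (!is.null(cv)) cv$fold_dev else NULL,
                 n = length(y)),
            class = "brt_eval")
}

#' @export
print.brt_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f (sensitivity %.2f, 1-specificity %.2f at threshold %.3f)\n",
              x$auc, x$sensitivity, x$one_minus_specificity, x$threshold))
  if (!is.na(x$cv_dev))
    cat(sprintf("CV deviance explained: %.1f%% (SE %.2f)\n", x$cv_dev,
                x$cv_dev_se))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `brt_model`.
#' @param path output path.
#' @param include_data store the training features/labels too (needed to
#'   recompute partial dependence after reloading).
#' @export
write_brt_model <- function(model, path, include_data = TRUE) {
  obj <- list(intercept = model$intercept, lr = model$lr, nt = model$nt,
              var_names = model$var_names, seed = model$seed,
              config = unclass(model$config),
              trees = lapply(model$trees, function(T) unname(as.matrix(T))))
  if (include_data) { obj$X <- unname(model$X); obj$y <- model$y }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_brt_model()]
#'
#' @param path JSON file.
#' @return a `brt_model`.
#' @export
read_brt_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  cfg <- do.call(brt_config, obj$config)
  X <- if (!is.null(obj$X)) as.matrix(obj$X) else NULL
  if (!is.null(X)) colnames(X) <- obj$var_names
  trees <- if (is.array(obj$trees) && length(dim(obj$trees)) == 3)
    lapply(seq_len(dim(obj$trees)[1]), function(i) obj$trees[i, , ])
  else lapply(obj$trees, as.matrix)
  structure(list(intercept = obj$intercept, lr = obj$lr,
                 nt = as.integer(obj$nt), trees = trees,
                 var_names = obj$var_names, X = X, y = unlist(obj$y),
                 train_dev = NULL, config = cfg, seed = obj$seed, cv = NULL),
            class = "brt_model")
}
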