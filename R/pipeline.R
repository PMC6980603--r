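#' Write a breeding-pair density map to GeoJSON
#'
#' One rectangular Feature per quadrant with properties `bp_class` (1-6),
#' `bp_lower` (lower class border) and the quadrant indices.
#'
#' @param map a [generate_density_map()] result.
#' @param path output path.
#' @export
write_density_geojson <- function(map, path) {
  qs <- map$quadrant_size
  features <- list()
  for (qr in seq_len(map$n_qrows)) {
    for (qc in seq_len(map$n_qcols)) {
      x0 <- map$origin[1] + (qc - 1) * qs
      y0 <- map$origin[2] + (qr - 1) * qs
      ring <- list(c(x0, y0), c(x0 + qs, y0), c(x0 + qs, y0 + qs),
                   c(x0, y0 + qs), c(x0, y0))
      k <- map$class_index[qr, qc]
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(bp_class = k, bp_lower = map$lower_borders[k],
                          qrow = qr, qcol = qc),
        geometry = list(type = "Polygon", coordinates = list(ring)))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a breeding-pair density map from GeoJSON
#'
#' @param path file written by [write_density_geojson()].
#' @return a `bp_density_map`.
#' @export
read_density_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  qr <- vapply(fc$features, function(f) f$properties$qrow, 0)
  qc <- vapply(fc$features, function(f) f$properties$qcol, 0)
  cl <- vapply(fc$features, function(f) f$properties$bp_class, 0)
  xy <- t(vapply(fc$features, function(f)
    as.numeric(unlist(f$geometry$coordinates[[1]][[1]])), numeric(2)))
  qs <- abs(as.numeric(unlist(fc$features[[1]]$geometry$coordinates[[1]][[2]]))[1] -
            xy[1, 1])
  cm <- matrix(NA_integer_, max(qr), max(qc))
  cm[cbind(qr, qc)] <- as.integer(cl)
  structure(list(origin = c(min(xy[, 1]), min(xy[, 2])), quadrant_size = qs,
                 n_qrows = max(qr), n_qcols = max(qc), class_index = cm,
                 lower_borders = bp_lower_borders()),
            class = "bp_density_map")
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one object with a single global
#' seed that fans out to per-stage random streams.
#'
#' @param seed global integer seed.
#' @param extent region extent in metres.
#' @param cell_size grid resolution in metres.
#' @param patch_scale landscape patch diameter in metres.
#' @param class_coverages named coverage targets (default [delv_classes()]).
#' @param n_turbines simulated turbine count.
#' @param status_props proportions over functional/approved/proposed.
#' @param risk generative [risk_spec()].
#' @param quadrant_size density quadrant edge (metres).
#' @param density_class_probs probabilities over the six density classes.
#' @param balance_ratio majority:minority cap for [downsample_balance()].
#' @param test_fraction held-out fraction of the training set.
#' @param brt a [brt_config()]; its seed is overridden by the global seed.
#' @param max_drop predictors dropped in simplification.
#' @param kde_bandwidth kernel bandwidth (metres) for density surfaces.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, extent = c(20000, 20000),
                            cell_size = 100, patch_scale = 1500,
                            class_coverages = NULL, n_turbines = 1200,
                            status_props = c(functional = 0.5,
                                             approved = 0.35,
                                             proposed = 0.15),
                            risk = default_risk_spec(),
                            quadrant_size = 5000,
                            density_class_probs = c(0.05, 0.10, 0.15, 0.30,
                                                    0.30, 0.10),
                            balance_ratio = 1, test_fraction = 0.3,
                            brt = brt_config(), max_drop = 2,
                            kde_bandwidth = 2000) {
  brt$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, patch_scale = patch_scale,
                 class_coverages = class_coverages, n_turbines = n_turbines,
                 status_props = status_props, risk = risk,
                 quadrant_size = quadrant_size,
                 density_class_probs = density_class_probs,
                 balance_ratio = balance_ratio,
                 test_fraction = test_fraction, brt = brt,
                 max_drop = max_drop, kde_bandwidth = kde_bandwidth),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' `brt` may be a nested block of [brt_config()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param seed optional seed override.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  if (!is.null(args$brt)) args$brt <- do.call(brt_config, as.list(args$brt))
  if (!is.null(args$status_props)) args$status_props <- unlist(args$status_props)
  if (!is.null(args$class_coverages)) args$class_coverages <- unlist(args$class_coverages)
  if (!is.null(args$extent)) args$extent <- as.numeric(args$extent)
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

stage_simulate <- function(config, dir) {
  cfg <- landscape_config(extent = config$extent,
                          cell_size = config$cell_size,
                          class_coverages = config$class_coverages,
                          patch_scale = config$patch_scale,
                          seed = seed_for(config$seed, 101L))
  ls <- generate_landscape(cfg)
  stack <- build_delv_stack(ls$layers, ls$grid)
  tb <- generate_turbines(config$n_turbines, ls$grid, config$status_props,
                          seed = seed_for(config$seed, 102L))
  tb <- simulate_collisions(tb, stack, config$risk,
                            seed = seed_for(config$seed, 103L))
  tb$outcome[tb$status != "functional"] <- NA_integer_  # unsearched
  carc_tb <- tb[tb$status == "functional", ]
  carcasses <- generate_carcasses(carc_tb, seed = seed_for(config$seed, 104L))
  dmap <- generate_density_map(ls$grid, config$quadrant_size,
                               config$density_class_probs,
                               seed = seed_for(config$seed, 105L))
  dir.create(file.path(dir, "layers"), recursive = TRUE, showWarnings = FALSE)
  for (ly in ls$layers)
    write_layer_geojson(ly, file.path(dir, "layers",
                                      paste0(ly$class, ".geojson")))
  utils::write.csv(tb, file.path(dir, "turbines.csv"), row.names = FALSE)
  utils::write.csv(carcasses, file.path(dir, "carcasses.csv"),
                   row.names = FALSE)
  write_density_geojson(dmap, file.path(dir, "density.geojson"))
  list(landscape = ls, stack = stack, turbines = tb, carcasses = carcasses,
       density = dmap)
}

stage_delv <- function(config, dir, stack = NULL) {
  if (is.null(stack)) {
    grid <- grid_from_extent(config$extent, config$cell_size)
    files <- list.files(file.path(dir, "layers"), full.names = TRUE)
    layers <- lapply(files, read_layer_geojson)
    stack <- build_delv_stack(layers, grid)
  }
  dir.create(file.path(dir, "delv"), showWarnings = FALSE)
  for (r in stack$rasters)
    write_ascii_grid(r, file.path(dir, "delv", paste0(r$name, ".asc")))
  stack
}

read_delv_stack <- function(dir, classes = delv_classes()) {
  rasters <- lapply(classes$acronym, function(a)
    read_ascii_grid(file.path(dir, "delv", paste0(a, ".asc"))))
  names(rasters) <- classes$acronym
  structure(list(grid = rasters[[1]]$grid, rasters = rasters,
                 classes = classes), class = "delv_stack")
}

stage_train <- function(config, dir, sim = NULL) {
  tb <- sim$turbines %||% utils::read.csv(file.path(dir, "turbines.csv"))
  carcasses <- sim$carcasses %||%
    utils::read.csv(file.path(dir, "carcasses.csv"))
  stack <- sim$stack %||% read_delv_stack(dir)
  labels <- label_turbines(carcasses)
  labels <- downsample_balance(labels, config$balance_ratio,
                               seed = seed_for(config$seed, 106L))
  lab_tb <- tb[match(labels$turbine_id, tb$id), ]
  feats <- cbind(data.frame(turbine_id = lab_tb$id),
                 sample_delv(stack, lab_tb))
  tset <- assemble_training_set(labels, feats)
  utils::write.csv(tset, file.path(dir, "training_set.csv"),
                   row.names = FALSE)
  # stratified train/test split
  test_idx <- withr::with_seed(seed_for(config$seed, 107L), {
    unlist(lapply(split(seq_len(nrow(tset)), tset$label), function(idx)
      sample(idx, round(config$test_fraction * length(idx)))))
  })
  train <- tset[-test_idx, ]
  test <- tset[test_idx, ]
  full <- brt_step(train, config$brt)
  simp <- brt_simplify(full, train, max_drop = config$max_drop)
  ev_full <- evaluate_brt(full, test)
  ev_simp <- evaluate_brt(simp$model, test)
  write_brt_model(full, file.path(dir, "model_full.json"))
  write_brt_model(simp$model, file.path(dir, "model_simplified.json"))
  jsonlite::write_json(
    list(full = unclass(ev_full)[c("auc", "sensitivity",
                                   "one_minus_specificity", "threshold",
                                   "cv_dev", "cv_dev_se")],
         simplified = unclass(ev_simp)[c("auc", "sensitivity",
                                         "one_minus_specificity",
                                         "threshold", "cv_dev",
                                         "cv_dev_se")],
         drops = simp$drops),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  list(training_set = tset, train = train, test = test, full = full,
       simplified = simp, eval_full = ev_full, eval_simplified = ev_simp)
}

stage_predict <- function(config, dir, model = NULL, stack = NULL) {
  model <- model %||% read_brt_model(file.path(dir, "model_simplified.json"))
  stack <- stack %||% read_delv_stack(dir)
  cp <- predict_cp_raster(model, stack)
  write_ascii_grid(cp, file.path(dir, "cp.asc"))
  cp
}

stage_susceptibility <- function(config, dir, cp = NULL, density = NULL) {
  cp <- cp %||% read_ascii_grid(file.path(dir, "cp.asc"))
  density <- density %||% read_density_geojson(file.path(dir, "density.geojson"))
  bpdrel <- relative_density(density, cp$grid)
  sc <- strike_susceptibility(cp, bpdrel)
  cls <- classify_sc(sc)
  write_ascii_grid(sc, file.path(dir, "sc.asc"))
  write_ascii_grid(cls, file.path(dir, "sc_class.asc"))
  list(sc = sc, classes = cls)
}

stage_report <- function(config, dir, turbines = NULL, classes = NULL) {
  turbines <- turbines %||% utils::read.csv(file.path(dir, "turbines.csv"))
  classes <- classes %||% read_ascii_grid(file.path(dir, "sc_class.asc"))
  planned <- turbines[turbines$status %in% c("approved", "proposed"), ]
  zt <- count_turbines_by_class(planned, classes,
                                statuses = c("approved", "proposed"))
  write_zone_counts(zt, file.path(dir, "zone_counts.csv"))
  func <- turbines[turbines$status == "functional", ]
  dens_t <- point_density_raster(func, config$kde_bandwidth, classes$grid)
  write_ascii_grid(dens_t, file.path(dir, "density_turbines.asc"))
  coll <- func[!is.na(func$outcome) & func$outcome == 1, ]
  dens_c <- point_density_raster(coll, config$kde_bandwidth, classes$grid)
  write_ascii_grid(dens_c, file.path(dir, "density_collisions.asc"))
  zt
}

#' Run the full collision-risk pipeline
#'
#' Executes synthetic data generation, distance-to-edge computation,
#' training-set assembly, stepped boosted-tree fitting with simplification
#' and evaluation, collision-potential prediction, strike-susceptibility
#' overlay, zone classification and turbine counting, writing every artifact
#' plus a JSON manifest (versions, seed, metrics, file hashes) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "collrisk_run") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- run_stage("simulate", stage_simulate(config, out_dir))
  run_stage("delv", stage_delv(config, out_dir, stack = sim$stack))
  tr <- run_stage("train", stage_train(config, out_dir, sim = sim))
  cp <- run_stage("predict",
                  stage_predict(config, out_dir, model = tr$simplified$model,
                                stack = sim$stack))
  sus <- run_stage("susceptibility",
                   stage_susceptibility(config, out_dir, cp = cp,
                                        density = sim$density))
  zt <- run_stage("report", stage_report(config, out_dir,
                                         turbines = sim$turbines,
                                         classes = sus$classes))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "collrisk",
    version = as.character(utils::packageVersion("collrisk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    metrics = list(
      n_training = nrow(tr$training_set),
      full = list(lr = tr$full$cv$lr, nt = tr$full$cv$nt,
                  cv_dev_explained = tr$full$cv$cv_dev_explained,
                  auc = tr$eval_full$auc),
      simplified = list(lr = tr$simplified$model$cv$lr,
                        nt = tr$simplified$model$cv$nt,
                        n_predictors = length(tr$simplified$model$var_names),
                        retained = tr$simplified$model$var_names,
                        dropped = tr$simplified$drops$dropped,
                        cv_dev_explained = tr$simplified$model$cv$cv_dev_explained,
                        auc = tr$eval_simplified$auc),
      zones = list(above60_count = attr(zt, "above60_count"),
                   above60_percent = attr(zt, "above60_percent"))),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin argument parser over the stage functions. Subcommands: `simulate`,
#' `delv`, `train`, `predict`, `susceptibility`, `report`, `run-all`.
#' Options: `--config <file>` (YAML/JSON), `--seed <int>`, `--out <dir>`,
#' `--log-level <level>`.
#'
#' @param args character vector (default the command line).
#' @return exit status 0 on success (invisibly); errors carry the failing
#'   stage in their message.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stopf("usage: collrisk <subcommand> [--config f] [--seed n] [--out dir]")
  cmd <- args[1]
  known <- c("run-all", "simulate", "delv", "train", "predict",
             "susceptibility", "report")
  if (!cmd %in% known) stopf("unknown subcommand '%s'", cmd)
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "collrisk_run")
  seed <- as.integer(opt("--seed", "1"))
  cfg_path <- opt("--config")
  config <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path, seed = seed)
            else pipeline_config(seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    "run-all" = run_pipeline(config, out),
    "simulate" = run_stage("simulate", stage_simulate(config, out)),
    "delv" = run_stage("delv", stage_delv(config, out)),
    "train" = run_stage("train", stage_train(config, out)),
    "predict" = run_stage("predict", stage_predict(config, out)),
    "susceptibility" = run_stage("susceptibility",
                                 stage_susceptibility(config, out)),
    "report" = run_stage("report", stage_report(config, out)),
    stopf("unknown subcommand '%s'", cmd))
  invisible(0L)
}
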