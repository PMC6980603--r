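#' One parameter-recovery simulation replicate
#'
#' Runs the full modelling protocol on one synthetic dataset with known
#' ground truth: generate a balanced training set under the default (or
#' given) risk model, hold out a stratified test fraction, select the
#' ensemble by the stepped cross-validated protocol, and summarise recovery
#' (held-out AUC, influence ranking, the top-ranked generative driver).
#' With `permute = TRUE` the training labels are permuted first, giving the
#' null reference against which recovery is judged.
#'
#' @param seed integer seed for this replicate (drives landscape, turbines,
#'   outcomes, folds and bagging).
#' @param n_per_class rows per label in the training set.
#' @param test_fraction stratified held-out fraction.
#' @param config a [brt_config()]; defaults to the standard protocol with
#'   this replicate's seed.
#' @param spec generative [risk_spec()].
#' @param permute permute labels before fitting (null model).
#' @return list with `model`, `eval`, `influence`, `top4` (variable names),
#'   `auc`, and `train`/`test` row indices.
#' @export
recovery_replicate <- function(seed, n_per_class = 200, test_fraction = 0.3,
                               config = NULL, spec = default_risk_spec(),
                               permute = FALSE) {
  config <- config %||% brt_config(seed = seed)
  ts <- synthetic_training_set(n_per_class = n_per_class, seed = seed,
                               spec = spec)
  if (permute)
    ts$label <- withr::with_seed(seed_for(seed, 51L), sample(ts$label))
  test_idx <- withr::with_seed(seed_for(seed, 52L), {
    unlist(lapply(split(seq_len(nrow(ts)), ts$label), function(i)
      sample(i, round(test_fraction * length(i)))))
  })
  model <- suppressWarnings(brt_step(ts[-test_idx, ], config))
  ev <- evaluate_brt(model, ts[test_idx, ])
  infl <- relative_influence(model)
  list(model = model, eval = ev, influence = infl,
       top4 = infl$variable[1:4], auc = ev$auc,
       training_set = ts, test_idx = test_idx)
}
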