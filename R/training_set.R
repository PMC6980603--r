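#' Label turbines from carcass-search records
#'
#' Applies the presence/pseudo-absence rules used to assemble the response:
#' a turbine with at least one target-species record is a presence; a turbine
#' whose only raptor records come from the target's taxonomic family (but not
#' the target itself) is excluded, because family-mates are neither reliable
#' presences of the target nor defensible absences; a turbine with records of
#' other bird groups only is a pseudo-absence. Turbines absent from the
#' record table are not labelled at all (they were not searched). Record
#' counts are ignored: only the turbine's identity matters.
#'
#' @param carcasses data.frame `turbine_id, species, family, count`.
#' @param target_species species whose collisions are modelled.
#' @param excluded_family taxonomic family excluded from pseudo-absences;
#'   must occur in the records, and the target species must belong to it.
#' @return data.frame `turbine_id, label` with label in
#'   `c("presence", "pseudo_absence", "excluded")`.
#' @export
label_turbines <- function(carcasses, target_species = "Buteo buteo",
                           excluded_family = "Accipitridae") {
  if (!excluded_family %in% carcasses$family)
    stopf("unknown family '%s': not present in the carcass records",
          excluded_family)
  tgt <- carcasses$species == target_species
  if (any(tgt) && any(carcasses$family[tgt] != excluded_family))
    stopf("target species '%s' does not belong to family '%s'",
          target_species, excluded_family)
  ids <- sort(unique(carcasses$turbine_id))
  has_target <- ids %in% carcasses$turbine_id[tgt]
  has_family <- ids %in% carcasses$turbine_id[!tgt &
                                              carcasses$family == excluded_family]
  label <- ifelse(has_target, "presence",
                  ifelse(has_family, "excluded", "pseudo_absence"))
  data.frame(turbine_id = ids, label = label, stringsAsFactors = FALSE)
}

#' Balance presences and pseudo-absences by down-sampling
#'
#' Randomly subsamples the majority label without replacement so that
#' neither label dominates; at the default 1:1 ratio the two counts end up
#' equal (to within one row).
#'
#' @param labeled data.frame `turbine_id, label`; rows labelled `"excluded"`
#'   are dropped first.
#' @param target_ratio maximum allowed majority:minority ratio (default 1).
#' @param seed integer seed.
#' @return the balanced label table.
#' @export
downsample_balance <- function(labeled, target_ratio = 1, seed = 1L) {
  keep <- labeled[labeled$label %in% c("presence", "pseudo_absence"), ]
  n_pres <- sum(keep$label == "presence")
  n_abs <- sum(keep$label == "pseudo_absence")
  if (n_pres == 0 || n_abs == 0)
    stopf("both presence and pseudo-absence labels are required (have %d / %d)",
          n_pres, n_abs)
  major <- if (n_pres >= n_abs) "presence" else "pseudo_absence"
  n_major <- max(n_pres, n_abs); n_minor <- min(n_pres, n_abs)
  target <- min(n_major, ceiling(target_ratio * n_minor))
  if (target < n_major) {
    idx <- which(keep$label == major)
    drop <- withr::with_seed(seed_for(seed, 7L),
                             sample(idx, n_major - target))
    keep <- keep[-drop, ]
  }
  rownames(keep) <- NULL
  keep
}

#' Join labels with distance features into a training set
#'
#' @param labeled balanced label table ([downsample_balance()]).
#' @param delv_features data.frame with `turbine_id` plus one signed-distance
#'   column per class acronym (e.g. [sample_delv()] output bound to ids).
#' @return a training-set data.frame: `turbine_id`, feature columns,
#'   `label` (1 = presence, 0 = pseudo-absence).
#' @export
assemble_training_set <- function(labeled, delv_features) {
  if (!nrow(labeled)) stopf("empty label table")
  miss <- setdiff(labeled$turbine_id, delv_features$turbine_id)
  if (length(miss))
    stopf("no feature rows for turbine(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  m <- merge(labeled, delv_features, by = "turbine_id", sort = TRUE)
  m$label <- as.integer(m$label == "presence")
  feat_cols <- setdiff(names(delv_features), "turbine_id")
  out <- m[, c("turbine_id", feat_cols, "label")]
  if (anyNA(out)) stopf("missing values in assembled training set")
  rownames(out) <- NULL
  out
}
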