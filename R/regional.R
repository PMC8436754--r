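#' Fraction of a brain region covered by the lesion mask
#'
#' The training target of the regional detector: the proportion of the
#' region's volume marked lesional, so a region 10% inside the lesion maps
#' to 0.1 and any region of a control subject to 0.
#'
#' @param parcellation a [parcellation_map].
#' @param region_id region label.
#' @param mask binary lesion lattice sharing geometry.
#' @return scalar in `[0, 1]`.
#' @export
lesion_fraction <- function(parcellation, region_id, mask) {
  region <- parcellation$labels == region_id
  n <- sum(region)
  if (n == 0L)
    stop("region ", region_id, " is empty", call. = FALSE)
  mask <- as_mask_array(mask)
  if (!all(dim(mask) == dim(region)))
    stop("mask geometry mismatch", call. = FALSE)
  sum(mask & region) / n
}

compartment_stats <- function(values) {
  c(mean = mean(values), sd = if (length(values) > 1L) sd(values) else 0)
}

#' Regional feature row: normalized volume plus shell appearance
#'
#' Computes the per-region input of the regional detector: the region's
#' normalized volume (region volume / total brain volume) followed by, for
#' every modality and each of the three compartments (core, inner shell,
#' outer shell), the mean and standard deviation of in-compartment
#' intensities — `1 + 6 * length(modalities)` features. A compartment
#' emptied by the 1 mm erosion (tiny regions) falls back to whole-region
#' statistics and is flagged.
#'
#' @param subject a [subject_study] (volumes already normalized where the
#'   configuration requires it).
#' @param region_id region label.
#' @param shells a `region_shells` from [extract_shells].
#' @param modalities modality tags to include (default: all the subject
#'   carries).
#' @return named numeric feature vector with attribute
#'   `"empty_compartment"` (TRUE if any fallback was used).
#' @export
regional_features <- function(subject, region_id, shells,
                              modalities = names(subject$volumes)) {
  stopifnot(inherits(subject, "subject_study"),
            inherits(shells, "region_shells"))
  brain <- brain_mask(subject$parcellation)
  region <- shells$core | shells$inner_shell
  voxvol <- prod(subject$parcellation$spacing)
  feats <- c(normalized_volume = sum(region) / sum(brain))
  comps <- list(core = shells$core, inner = shells$inner_shell,
                outer = shells$outer_shell)
  fallback <- FALSE
  for (mod in modalities) {
    vol <- subject$volumes[[mod]]$data
    parent <- compartment_stats(vol[region])
    for (cn in names(comps)) {
      cm <- comps[[cn]]
      if (any(cm)) st <- compartment_stats(vol[cm])
      else { st <- parent; fallback <- TRUE }
      names(st) <- paste(mod, cn, c("mean", "sd"), sep = "_")
      feats <- c(feats, st)
    }
  }
  attr(feats, "empty_compartment") <- fallback
  feats
}

#' Build the regional feature table for a set of subjects
#'
#' One row per (subject, region) with the feature schema of
#' [regional_features], the fractional-lesion target, and a provenance
#' flag for empty-compartment fallbacks. The schema is identical across
#' subjects; in a cohort sharing one parcellation pass precomputed
#' `shells` from [extract_all_shells] to avoid recomputation.
#'
#' @param subjects list of [subject_study].
#' @param shells named list of `region_shells` (one per region id); if
#'   NULL, computed from the first subject's parcellation.
#' @param modalities modality tags entering the regional detector.
#' @param thickness_mm shell thickness used when `shells` is NULL.
#' @return data.frame with columns `subject_id`, `region_id`,
#'   `lesion_fraction`, `empty_compartment`, then the feature columns
#'   (attribute `"feature_cols"` names them).
#' @export
build_regional_table <- function(subjects, shells = NULL,
                                 modalities = NULL, thickness_mm = 1.0) {
  if (inherits(subjects, "subject_study")) subjects <- list(subjects)
  if (is.null(modalities)) modalities <- names(subjects[[1]]$volumes)
  if (is.null(shells))
    shells <- extract_all_shells(subjects[[1]]$parcellation, thickness_mm)
  rows <- list()
  for (subj in subjects) {
    ids <- subj$parcellation$region_ids
    for (id in ids) {
      sh <- shells[[as.character(id)]]
      f <- regional_features(subj, id, sh, modalities)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, region_id = id,
        lesion_fraction = lesion_fraction(subj$parcellation, id,
                                          subj$lesion_mask),
        empty_compartment = attr(f, "empty_compartment"),
        t(unclass(f)), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "feature_cols") <-
    setdiff(colnames(tab), c("subject_id", "region_id",
                             "lesion_fraction", "empty_compartment"))
  tab
}

regional_feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc))
    fc <- setdiff(colnames(table),
                  c("subject_id", "region_id", "lesion_fraction",
                    "empty_compartment"))
  fc
}

#' Default gradient-boosting hyperparameters for the regional regressor
#' @param nrounds,max_depth,eta boosting rounds, tree depth, learning rate.
#' @return list of hyperparameters.
#' @export
c1_params <- function(nrounds = 200, max_depth = 6, eta = 0.05) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta)
}

#' Train the regional abnormality regressor (first stage)
#'
#' Fits a gradient-boosted decision-tree ensemble regressing the regional
#' feature rows onto the fractional lesion volume of each region.
#' Controls (all-zero targets) belong in the training table — they teach
#' the model normal regional appearance — but a table with *only* zero
#' targets is degenerate and refused. Training is deterministic for a
#' fixed seed (single-threaded).
#'
#' @param table a regional feature table from [build_regional_table].
#' @param params hyperparameters from [c1_params].
#' @param seed integer seed.
#' @return An object of class `c1_model`.
#' @export
train_c1 <- function(table, params = c1_params(), seed = 1L) {
  fc <- regional_feature_cols(table)
  y <- table$lesion_fraction
  if (all(y == 0))
    stop("degenerate training table: every lesion_fraction is 0 ",
         "(no positive subject rows)", call. = FALSE)
  X <- as.matrix(table[, fc, drop = FALSE])
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = params$max_depth, eta = params$eta,
                  tree_method = "hist", nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
  structure(list(booster = booster, feature_cols = fc, params = params,
                 seed = seed),
            class = "c1_model")
}

#' Predict regional lesion fractions, clipped to [0, 1]
#'
#' @param model a `c1_model`.
#' @param table a regional feature table with the training schema.
#' @return numeric vector of predicted fractions, one per row.
#' @export
predict_c1 <- function(model, table) {
  fc <- regional_feature_cols(table)
  if (!identical(fc, model$feature_cols))
    stop("feature schema mismatch between model and table", call. = FALSE)
  X <- as.matrix(table[, fc, drop = FALSE])
  p <- predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  pmin(pmax(p, 0), 1)
}

#' Render the regional abnormality probability map (RAP)
#'
#' Scores every region of a subject with the regional regressor and
#' renders the scores voxelwise: each voxel of region r carries score(r),
#' background carries 0. This map is the stacked input of the voxelwise
#' detector.
#'
#' @param model a `c1_model`.
#' @param subject a [subject_study].
#' @param shells precomputed shells ([extract_all_shells]) or NULL.
#' @param modalities modality tags matching the training schema.
#' @param thickness_mm shell thickness used when `shells` is NULL.
#' @return A [volume_grid] (modality `"rap"`) with per-region scores
#'   attached as attribute `"scores"` (named by region id).
#' @export
predict_rap <- function(model, subject, shells = NULL, modalities = NULL,
                        thickness_mm = 1.0) {
  tab <- build_regional_table(list(subject), shells = shells,
                              modalities = modalities,
                              thickness_mm = thickness_mm)
  scores <- predict_c1(model, tab)
  lut <- rep(0, max(subject$parcellation$region_ids) + 1L)
  lut[tab$region_id + 1L] <- scores
  rap <- array(lut[subject$parcellation$labels + 1L],
               dim = dim(subject$parcellation$labels))
  out <- volume_grid(rap, spacing = subject$parcellation$spacing,
                     affine = subject$parcellation$affine,
                     modality = "rap")
  attr(out, "scores") <- setNames(scores, tab$region_id)
  out
}
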