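# Resolve a C2 input volume tag to its data array. "rap" is the rendered
# first-stage map, "thickness" the cortical-thickness map; anything else
# must be a modality the subject carries.
c2_volume_array <- function(subject, rap, tag) {
  if (tag == "rap") {
    if (is.null(rap))
      stop("the 'rap' input volume requires a regional abnormality map",
           call. = FALSE)
    return(rap$data)
  }
  if (tag == "thickness") return(subject$cortical_thickness$data)
  if (!tag %in% names(subject$volumes))
    stop("subject ", subject$subject_id, " is missing the configured ",
         "modality '", tag, "'", call. = FALSE)
  subject$volumes[[tag]]$data
}

# centre + 6 face-neighbour intensities for sampled voxels; neighbours
# outside the lattice or outside the brain replicate the centre value
neighbor_block <- function(arr, idx, brain) {
  dims <- dim(arr)
  centre <- arr[idx]
  out <- matrix(0, nrow(idx), 7L)
  out[, 1L] <- centre
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (q in 1:6) {
    ni <- sweep(idx, 2L, offs[q, ], `+`)
    ok <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
          ni[, 2] >= 1 & ni[, 2] <= dims[2] &
          ni[, 3] >= 1 & ni[, 3] <= dims[3]
    if (any(ok)) ok[ok] <- brain[ni[ok, , drop = FALSE]]
    vals <- centre
    if (any(ok)) vals[ok] <- arr[ni[ok, , drop = FALSE]]
    out[, q + 1L] <- vals
  }
  out
}

#' Voxelwise feature matrix for the second-stage classifier
#'
#' For every sampled voxel: the signal intensity of the voxel itself plus
#' its six immediate face neighbours in 3-D, on each configured input
#' volume (by default the rendered regional abnormality map, the imaging
#' contrasts and the cortical-thickness map), plus the voxel's
#' parcellation label as spatial context — `7 * n_volumes + 1` columns.
#' Neighbours falling outside the lattice or outside the brain replicate
#' the centre value, so the matrix never contains missing cells. Labels
#' come from the lesion mask (1 inside, 0 outside; all 0 for controls).
#'
#' @param subject a [subject_study].
#' @param rap rendered regional abnormality map ([predict_rap]) or NULL
#'   when `"rap"` is not among `volumes`.
#' @param sample n x 3 matrix of 1-based voxel indices, all inside the
#'   brain mask.
#' @param volumes character vector of input-volume tags.
#' @return list with `X` (feature matrix), `y` (0/1 labels) and
#'   `provenance` (data.frame subject_id, i, j, k).
#' @export
voxel_features <- function(subject, rap, sample,
                           volumes = c("rap", "t1", "flair", "ndi",
                                       "ad", "fa", "rd", "thickness")) {
  stopifnot(inherits(subject, "subject_study"))
  sample <- matrix(as.integer(sample), ncol = 3L)
  brain <- brain_mask(subject$parcellation)
  if (!all(brain[sample]))
    stop("sampled voxels must lie inside the brain mask", call. = FALSE)
  blocks <- vector("list", length(volumes))
  for (v in seq_along(volumes)) {
    arr <- c2_volume_array(subject, rap, volumes[v])
    if (!all(dim(arr) == dim(brain)))
      stop("geometry mismatch for input volume '", volumes[v], "'",
           call. = FALSE)
    b <- neighbor_block(arr, sample, brain)
    colnames(b) <- paste(volumes[v],
                         c("c", "xm", "xp", "ym", "yp", "zm", "zp"),
                         sep = "_")
    blocks[[v]] <- b
  }
  X <- do.call(cbind, blocks)
  X <- cbind(X, region_label = as.numeric(
    subject$parcellation$labels[sample]))
  y <- as.integer(subject$lesion_mask[sample])
  list(X = X, y = y,
       provenance = data.frame(subject_id = subject$subject_id,
                               i = sample[, 1], j = sample[, 2],
                               k = sample[, 3],
                               stringsAsFactors = FALSE))
}

#' Sample training voxels with background subsampling
#'
#' All lesional voxels of every positive subject are retained; background
#' voxels are subsampled uniformly at random to `ratio` times the lesional
#' count per positive subject (clamped, with a warning, when fewer are
#' available). Control subjects contribute a fixed per-subject quota of
#' background voxels. Sampling is deterministic for a fixed seed.
#'
#' @param subjects list of [subject_study].
#' @param ratio background : lesion ratio (>= 1).
#' @param control_quota background voxels per control subject.
#' @param seed integer seed.
#' @return named list of n x 3 voxel-index matrices, one per subject.
#' @export
sample_training_voxels <- function(subjects, ratio = 10,
                                   control_quota = 1000, seed = 1L) {
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- vector("list", length(subjects))
  names(out) <- vapply(subjects, function(s) s$subject_id, character(1))
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    brain <- brain_mask(subj$parcellation)
    lesional <- which(subj$lesion_mask & brain)
    background <- which(brain & !subj$lesion_mask)
    if (length(lesional) > 0L) {
      want <- round(ratio * length(lesional))
      if (want > length(background)) {
        warning("subject ", subj$subject_id, ": only ",
                length(background), " background voxels available (",
                want, " requested); taking all")
        want <- length(background)
      }
      keep <- c(lesional, sample(background, want))
    } else {
      keep <- sample(background, min(control_quota, length(background)))
    }
    out[[s]] <- matrix(arrayInd(keep, dim(brain)), ncol = 3L)
  }
  out
}

#' Default gradient-boosting hyperparameters for the voxelwise classifier
#' @param nrounds,max_depth,eta boosting rounds, tree depth, learning rate.
#' @return list of hyperparameters.
#' @export
c2_params <- function(nrounds = 150, max_depth = 6, eta = 0.08) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta)
}

c2_feature_types <- function(feature_names) {
  ifelse(feature_names == "region_label", "c", "q")
}

#' Train the voxelwise abnormality classifier (second stage)
#'
#' Gradient-boosted decision-tree ensemble mapping voxel feature rows to
#' the probability that the centre voxel is lesional. The parcellation
#' label column is declared categorical, so trees partition regions by
#' identity rather than by label arithmetic. Deterministic for a fixed
#' seed (single-threaded).
#'
#' @param X feature matrix from [voxel_features] (possibly row-bound
#'   across subjects).
#' @param y 0/1 labels.
#' @param params hyperparameters from [c2_params].
#' @param seed integer seed.
#' @return An object of class `c2_model`.
#' @export
train_c2 <- function(X, y, params = c2_params(), seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("voxelwise training matrix contains a single class",
         call. = FALSE)
  set.seed(seed)
  ft <- c2_feature_types(colnames(X))
  dtrain <- xgboost::xgb.DMatrix(X, label = y, feature_types = ft,
                                 nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  tree_method = "hist", nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
  structure(list(booster = booster, feature_cols = colnames(X),
                 params = params, seed = seed),
            class = "c2_model")
}

#' Per-row probabilities from the voxelwise classifier
#' @param model a `c2_model`.
#' @param X feature matrix with the training schema.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_c2 <- function(model, X) {
  if (!identical(colnames(X), model$feature_cols))
    stop("feature schema mismatch between model and matrix",
         call. = FALSE)
  ft <- c2_feature_types(colnames(X))
  predict(model$booster,
          xgboost::xgb.DMatrix(X, feature_types = ft, nthread = 1))
}

#' Assemble the final probabilistic abnormality map for one subject
#'
#' Scores every brain voxel with the voxelwise classifier (0 outside the
#' brain) and thresholds the probabilities into a binary lesion mask.
#'
#' @param model a `c2_model`.
#' @param subject a [subject_study].
#' @param rap rendered regional abnormality map, or NULL when the model
#'   was trained without the `"rap"` input.
#' @param volumes input-volume tags matching the training configuration.
#' @param threshold binarisation threshold in `(0, 1]`.
#' @return An [abnormality_map].
#' @export
predict_abnormality_map <- function(model, subject, rap,
                                    volumes = c("rap", "t1", "flair",
                                                "ndi", "ad", "fa", "rd",
                                                "thickness"),
                                    threshold = 0.5) {
  brain <- brain_mask(subject$parcellation)
  idx <- matrix(arrayInd(which(brain), dim(brain)), ncol = 3L)
  vf <- voxel_features(subject, rap, idx, volumes = volumes)
  p <- predict_c2(model, vf$X)
  probs <- array(0, dim = dim(brain))
  probs[brain] <- p
  pg <- volume_grid(probs, spacing = subject$parcellation$spacing,
                    affine = subject$parcellation$affine,
                    modality = "abnormality_probability")
  abnormality_map(pg, threshold = threshold)
}
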