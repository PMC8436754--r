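#' Detector configuration for the two-stage pipeline
#'
#' Collects everything the training and evaluation harness needs: the
#' modality list of the regional stage, the input-volume list of the
#' voxelwise stage (the rendered regional map, imaging contrasts and
#' cortical thickness), which contrasts are z-scored, shell thickness,
#' background sampling, binarisation threshold and per-stage
#' hyperparameters. The two stages carry separate modality lists because
#' contrasts can be informative regionally without helping voxelwise.
#'
#' @param c1_modalities modality tags entering the regional stage; NULL
#'   means every modality a subject carries.
#' @param c2_volumes input-volume tags of the voxelwise stage; NULL means
#'   `"rap"`, the imaging contrasts shared with `c1_modalities`, and
#'   `"thickness"`.
#' @param normalize tags z-scored over the brain mask before feature
#'   extraction (raw structural contrasts).
#' @param shell_thickness_mm boundary-shell thickness in mm.
#' @param ratio background : lesion voxel sampling ratio.
#' @param control_quota background voxels sampled per control subject.
#' @param threshold binarisation threshold of the probabilistic map.
#' @param c1,c2 hyperparameter lists from [c1_params] / [c2_params].
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(c1_modalities = NULL, c2_volumes = NULL,
                            normalize = c("t1", "flair", "swi"),
                            shell_thickness_mm = 1.0, ratio = 10,
                            control_quota = 1000, threshold = 0.5,
                            c1 = c1_params(), c2 = c2_params()) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)", call. = FALSE)
  structure(list(c1_modalities = c1_modalities, c2_volumes = c2_volumes,
                 normalize = normalize,
                 shell_thickness_mm = shell_thickness_mm, ratio = ratio,
                 control_quota = control_quota, threshold = threshold,
                 c1 = c1, c2 = c2),
            class = "detector_config")
}

# fill NULL modality lists from what the subjects actually carry
resolve_config <- function(config, subject) {
  mods <- names(subject$volumes)
  if (is.null(config$c1_modalities)) config$c1_modalities <- mods
  if (is.null(config$c2_volumes))
    config$c2_volumes <- c("rap", intersect(mods, config$c1_modalities),
                           "thickness")
  config
}

#' Z-score a subject's raw structural contrasts in place
#' @param subject a [subject_study].
#' @param tags modality tags to normalize (others pass through).
#' @return the subject with the named volumes z-scored over the brain
#'   mask.
#' @export
normalize_study <- function(subject, tags = c("t1", "flair", "swi")) {
  bm <- brain_mask(subject$parcellation)
  for (tag in intersect(tags, names(subject$volumes)))
    subject$volumes[[tag]] <- normalize_intensities(subject$volumes[[tag]],
                                                    bm)
  subject
}

# Cross-fitted first-stage scores for stacking: each training subject's
# regional scores come from a C1 fitted on the other groups, so the
# second stage never sees in-sample (memorised) first-stage predictions.
# Groups are stratified over positives and controls; a group is usable
# only if its complement still contains positive targets.
crossfit_c1_scores <- function(rtab, params, seed, k = 5L) {
  per_subj <- tapply(rtab$lesion_fraction, rtab$subject_id, max)
  uids <- names(per_subj)
  k <- max(2L, min(k, length(uids)))
  grp <- integer(length(uids)); names(grp) <- uids
  set.seed(seed)
  for (cls in list(uids[per_subj > 0], uids[per_subj == 0])) {
    if (length(cls))
      grp[sample(cls)] <- rep_len(seq_len(k), length(cls))
  }
  out <- vector("list", length(uids)); names(out) <- uids
  for (g in seq_len(k)) {
    out_ids <- uids[grp == g]
    if (!length(out_ids)) next
    in_rows <- !(rtab$subject_id %in% out_ids)
    m <- train_c1(rtab[in_rows, , drop = FALSE], params, seed)
    for (id in out_ids) {
      rows <- rtab$subject_id == id
      out[[id]] <- data.frame(region_id = rtab$region_id[rows],
                              score = predict_c1(m,
                                                 rtab[rows, ,
                                                      drop = FALSE]))
    }
  }
  out
}

# render per-region scores into a voxel lattice (background 0)
render_region_scores <- function(parcellation, region_ids, scores) {
  lut <- rep(0, max(parcellation$region_ids) + 1L)
  lut[region_ids + 1L] <- scores
  arr <- array(lut[parcellation$labels + 1L],
               dim = dim(parcellation$labels))
  volume_grid(arr, spacing = parcellation$spacing,
              affine = parcellation$affine, modality = "rap")
}

#' Train the full two-stage detector on a set of subjects
#'
#' Normalizes the configured contrasts, builds the regional feature table
#' and fits the regional regressor, renders each training subject's
#' regional abnormality map, then samples voxels and fits the voxelwise
#' classifier on the stacked features.
#'
#' @param subjects list of [subject_study] (positives and controls).
#' @param config a [detector_config].
#' @param seed integer seed governing voxel sampling and both fits.
#' @return An object of class `detector_bundle` with elements `c1`, `c2`
#'   and the resolved `config`.
#' @export
train_detector <- function(subjects, config = detector_config(),
                           seed = 1L) {
  config <- resolve_config(config, subjects[[1]])
  subjects <- lapply(subjects, normalize_study, tags = config$normalize)
  shells <- extract_all_shells(subjects[[1]]$parcellation,
                               config$shell_thickness_mm)
  rtab <- build_regional_table(subjects, shells = shells,
                               modalities = config$c1_modalities)
  c1 <- train_c1(rtab, params = config$c1, seed = seed)
  use_rap <- "rap" %in% config$c2_volumes
  cf <- if (use_rap) crossfit_c1_scores(rtab, config$c1, seed) else NULL
  samples <- sample_training_voxels(subjects, ratio = config$ratio,
                                    control_quota = config$control_quota,
                                    seed = seed)
  Xs <- list(); ys <- list()
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    rap <- if (use_rap) {
      sc <- cf[[subj$subject_id]]
      render_region_scores(subj$parcellation, sc$region_id, sc$score)
    } else NULL
    vf <- voxel_features(subj, rap, samples[[s]],
                         volumes = config$c2_volumes)
    Xs[[s]] <- vf$X; ys[[s]] <- vf$y
  }
  c2 <- train_c2(do.call(rbind, Xs), unlist(ys), params = config$c2,
                 seed = seed)
  structure(list(c1 = c1, c2 = c2, config = config, seed = seed),
            class = "detector_bundle")
}

#' Apply a trained detector bundle to one subject
#'
#' @param bundle a `detector_bundle` from [train_detector].
#' @param subject a [subject_study] (raw; normalization is applied with
#'   the bundle's configuration).
#' @return An [abnormality_map].
#' @export
predict_detector <- function(bundle, subject) {
  config <- bundle$config
  subject <- normalize_study(subject, tags = config$normalize)
  rap <- if ("rap" %in% config$c2_volumes)
    predict_rap(bundle$c1, subject, modalities = config$c1_modalities,
                thickness_mm = config$shell_thickness_mm) else NULL
  predict_abnormality_map(bundle$c2, subject, rap,
                          volumes = config$c2_volumes,
                          threshold = config$threshold)
}

loocv_summary <- function(rows) {
  qs <- function(v) {
    v <- v[is.finite(v)]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], iqr_lo = q[1], iqr_hi = q[3])
  }
  list(dice = qs(rows$dice), sensitivity = qs(rows$sensitivity),
       specificity = qs(rows$specificity))
}

#' Leave-one-out cross-validation over the positive subjects
#'
#' Every positive subject is held out in turn; both stages are trained
#' from scratch on the remaining positives plus all controls (controls
#' are never held out — control evaluation is a separate specificity
#' check) and the held-out subject is scored against its truth mask with
#' Dice, sensitivity and specificity (within the brain mask) and
#' predicted vs true lesion volume in mm^3.
#'
#' The regional feature table and the non-RAP voxel features depend only
#' on each subject's own data, so they are computed once and subset per
#' fold; only the fold-specific models and rendered regional maps are
#' recomputed, with identical voxel samples across folds.
#'
#' @param cohort a `phantom_cohort` or plain list of [subject_study].
#' @param config a [detector_config].
#' @param seed integer seed.
#' @param oracle if TRUE the truth mask is injected as the prediction
#'   (harness self-test; no models are trained).
#' @return An object of class `loocv_result`: `per_subject` data.frame,
#'   `summary` (median and IQR of each metric), `folds` (held-out and
#'   training subject ids), `config`, `seed`.
#' @export
run_loocv <- function(cohort, config = detector_config(), seed = 1L,
                      oracle = FALSE) {
  subjects <- if (inherits(cohort, "phantom_cohort")) cohort$subjects
              else cohort
  groups <- vapply(subjects, function(s) s$group, character(1))
  pos_idx <- which(groups == "mri_positive")
  if (length(pos_idx) < 2L)
    stop("LOOCV needs at least 2 positive subjects", call. = FALSE)
  if (sum(groups != "mri_positive") < 1L)
    stop("LOOCV needs at least 1 control subject", call. = FALSE)
  config <- resolve_config(config, subjects[[1]])
  voxvol <- prod(subjects[[1]]$parcellation$spacing)
  brain <- brain_mask(subjects[[1]]$parcellation)

  rows <- list(); folds <- list()
  if (oracle) {
    for (h in pos_idx) {
      subj <- subjects[[h]]
      truth <- subj$lesion_mask
      ss <- sensitivity_specificity(truth, truth, brain)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id,
        dice = dice_coefficient(truth, truth),
        sensitivity = ss[["sensitivity"]],
        specificity = ss[["specificity"]],
        pred_volume_mm3 = sum(truth) * voxvol,
        truth_volume_mm3 = sum(truth) * voxvol,
        stringsAsFactors = FALSE)
      folds[[length(folds) + 1L]] <- list(
        held_out = subj$subject_id,
        train_subjects = vapply(subjects[-h], function(s) s$subject_id,
                                character(1)))
    }
  } else {
    subjects <- lapply(subjects, normalize_study, tags = config$normalize)
    shells <- extract_all_shells(subjects[[1]]$parcellation,
                                 config$shell_thickness_mm)
    rtab <- build_regional_table(subjects, shells = shells,
                                 modalities = config$c1_modalities)
    samples <- sample_training_voxels(subjects, ratio = config$ratio,
                                      control_quota =
                                        config$control_quota,
                                      seed = seed)
    use_rap <- "rap" %in% config$c2_volumes
    static_vols <- setdiff(config$c2_volumes, "rap")
    # per-subject feature blocks that do not depend on the fold
    static <- vector("list", length(subjects))
    for (s in seq_along(subjects)) {
      vf <- voxel_features(subjects[[s]], NULL, samples[[s]],
                           volumes = static_vols)
      static[[s]] <- vf
    }
    rap_cols <- paste("rap", c("c", "xm", "xp", "ym", "yp", "zm", "zp"),
                      sep = "_")
    for (h in pos_idx) {
      held <- subjects[[h]]
      train_set <- setdiff(seq_along(subjects), h)
      rtab_f <- rtab[rtab$subject_id != held$subject_id, , drop = FALSE]
      c1_f <- train_c1(rtab_f, params = config$c1, seed = seed)
      cf_f <- if (use_rap) crossfit_c1_scores(rtab_f, config$c1, seed)
              else NULL
      Xs <- list(); ys <- list()
      for (s in train_set) {
        X <- static[[s]]$X
        if (use_rap) {
          sc <- cf_f[[subjects[[s]]$subject_id]]
          rap <- render_region_scores(subjects[[s]]$parcellation,
                                      sc$region_id, sc$score)
          rb <- neighbor_block(rap$data, samples[[s]], brain)
          colnames(rb) <- rap_cols
          # keep the configured column order: rap family first
          X <- cbind(rb, X[, setdiff(colnames(X), "region_label"),
                           drop = FALSE],
                     region_label = X[, "region_label"])
        }
        Xs[[length(Xs) + 1L]] <- X
        ys[[length(ys) + 1L]] <- static[[s]]$y
      }
      c2_f <- train_c2(do.call(rbind, Xs), unlist(ys),
                       params = config$c2, seed = seed)
      rap_h <- if (use_rap) {
        rws <- rtab$subject_id == held$subject_id
        render_region_scores(held$parcellation, rtab$region_id[rws],
                             predict_c1(c1_f, rtab[rws, , drop = FALSE]))
      } else NULL
      vols_pred <- if (use_rap) c("rap", static_vols) else static_vols
      amap <- predict_abnormality_map(c2_f, held, rap_h,
                                      volumes = vols_pred,
                                      threshold = config$threshold)
      truth <- held$lesion_mask
      ss <- sensitivity_specificity(amap$binary, truth, brain)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = held$subject_id,
        dice = dice_coefficient(amap$binary, truth),
        sensitivity = ss[["sensitivity"]],
        specificity = ss[["specificity"]],
        pred_volume_mm3 = sum(amap$binary) * voxvol,
        truth_volume_mm3 = sum(truth) * voxvol,
        stringsAsFactors = FALSE)
      folds[[length(folds) + 1L]] <- list(
        held_out = held$subject_id,
        train_subjects = vapply(subjects[train_set],
                                function(s) s$subject_id, character(1)))
    }
  }
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  structure(list(per_subject = per_subject,
                 summary = loocv_summary(per_subject), folds = folds,
                 config = config, seed = seed),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  s <- x$summary
  cat("<loocv_result> ", nrow(x$per_subject), " folds\n",
      sprintf("  median DSC %.3f (IQR %.3f-%.3f)\n", s$dice["median"],
              s$dice["iqr_lo"], s$dice["iqr_hi"]),
      sprintf("  median sensitivity %.3f, median specificity %.4f\n",
              s$sensitivity["median"], s$specificity["median"]),
      sep = "")
  invisible(x)
}

#' Ablation harness: withhold the regional stage or single modalities
#'
#' Re-runs the LOOCV under modified configurations: `no_c1` withholds the
#' rendered regional abnormality map from the voxelwise stage; each
#' `minus_<modality>` condition removes that modality from both stages.
#' Every condition retrains from scratch under the same seed, so voxel
#' samples are identical across conditions.
#'
#' @param cohort as for [run_loocv].
#' @param config a [detector_config].
#' @param seed integer seed.
#' @param conditions subset of condition labels to run; NULL runs
#'   `"full"`, `"no_c1"` and one `minus_<m>` per configured modality.
#'   `"full"` is always included.
#' @return data.frame with columns `condition`, `median_dsc`,
#'   `delta_vs_full`; the full [run_loocv] results are attached as
#'   attribute `"results"`.
#' @export
run_ablations <- function(cohort, config = detector_config(), seed = 1L,
                          conditions = NULL) {
  subjects <- if (inherits(cohort, "phantom_cohort")) cohort$subjects
              else cohort
  config <- resolve_config(config, subjects[[1]])
  mods <- config$c1_modalities
  if (is.null(conditions))
    conditions <- c("full", "no_c1", paste0("minus_", mods))
  conditions <- union("full", conditions)
  results <- list()
  for (cond in conditions) {
    cfg <- config
    if (cond == "no_c1") {
      cfg$c2_volumes <- setdiff(cfg$c2_volumes, "rap")
    } else if (grepl("^minus_", cond)) {
      m <- sub("^minus_", "", cond)
      if (!m %in% mods)
        stop("unknown modality in condition '", cond, "'", call. = FALSE)
      cfg$c1_modalities <- setdiff(cfg$c1_modalities, m)
      cfg$c2_volumes <- setdiff(cfg$c2_volumes, m)
      if (length(cfg$c1_modalities) == 0L)
        stop("removing '", m, "' leaves no modality", call. = FALSE)
    } else if (cond != "full")
      stop("unknown condition '", cond, "'", call. = FALSE)
    results[[cond]] <- run_loocv(cohort, cfg, seed = seed)
  }
  med <- vapply(results, function(r) r$summary$dice[["median"]],
                numeric(1))
  out <- data.frame(condition = names(results), median_dsc = med,
                    delta_vs_full = med - med[["full"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Two-tailed Mann-Whitney U comparison of lesion volumes
#'
#' Rank-sum test between predicted and manually traced lesion volumes.
#' For `n1 + n2 <= 12` the two-tailed p-value is exact, by enumeration of
#' all group assignments (ties handled through midranks); above that a
#' normal approximation with continuity and tie correction is used.
#'
#' @param pred_volumes,truth_volumes numeric vectors (mm^3), nonempty.
#' @return list with `statistic` (U of the first sample), `p.value` and
#'   `method`.
#' @export
compare_lesion_volumes <- function(pred_volumes, truth_volumes) {
  x <- as.numeric(pred_volumes); y <- as.numeric(truth_volumes)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stop("both volume lists must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= 12L) {
    combos <- combn(N, n1)
    Us <- apply(combos, 2L,
                function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = U, p.value = p, method = method)
}
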