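#' Write a phantom cohort to disk as NIfTI + manifests
#'
#' One directory per subject containing a NIfTI per modality, the shared
#' parcellation, the cortical-thickness map and the lesion mask (uint8),
#' plus a per-subject manifest (JSON: modality tag -> file). At the top
#' level, `cohort_manifest.json` lists every written file with the
#' configuration hash and seed, and `truth.json` records per-subject
#' lesion metadata.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the cohort manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cohort$config))
  files <- list()
  for (id in names(cohort$subjects)) {
    subj <- cohort$subjects[[id]]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    entry <- list(subject_id = id, group = subj$group, volumes = list())
    for (mod in names(subj$volumes)) {
      f <- file.path(sdir, paste0(mod, ".nii.gz"))
      write_volume(subj$volumes[[mod]], f)
      entry$volumes[[mod]] <- f
    }
    pf <- file.path(sdir, "parcellation.nii.gz")
    write_volume(volume_grid(subj$parcellation$labels,
                             subj$parcellation$spacing,
                             subj$parcellation$affine), pf,
                 datatype = "int16")
    tf <- file.path(sdir, "thickness.nii.gz")
    write_volume(subj$cortical_thickness, tf)
    mf <- file.path(sdir, "lesion_mask.nii.gz")
    write_volume(volume_grid(array(as.integer(subj$lesion_mask),
                                   dim = dim(subj$lesion_mask)),
                             subj$parcellation$spacing,
                             subj$parcellation$affine), mf,
                 datatype = "uint8")
    entry$parcellation <- pf
    entry$thickness <- tf
    entry$lesion_mask <- mf
    jsonlite::write_json(entry, file.path(sdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    files[[id]] <- entry
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(config_hash = hash, seed = cohort$config$seed,
                   subjects = files)
  out <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Read one subject back from a manifest written by [write_cohort]
#'
#' @param manifest_path path to a subject `manifest.json`.
#' @return A [subject_study].
#' @export
read_subject <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  locate <- function(p) if (file.exists(p)) p
                        else file.path(base, basename(p))
  volumes <- lapply(names(m$volumes), function(mod)
    read_volume(locate(m$volumes[[mod]]), modality = mod))
  names(volumes) <- names(m$volumes)
  pg <- read_volume(locate(m$parcellation))
  parc <- parcellation_map(array(as.integer(round(pg$data)),
                                 dim = dim(pg$data)),
                           spacing = pg$spacing, affine = pg$affine)
  thick <- read_volume(locate(m$thickness), modality = "thickness")
  mask <- read_volume(locate(m$lesion_mask))$data
  subject_study(m$subject_id, m$group, volumes, parc, thick,
                lesion_mask = mask)
}

#' Read a whole cohort from its manifest
#' @param manifest_path path to `cohort_manifest.json`.
#' @return list of [subject_study].
#' @export
read_cohort <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  subjects <- lapply(names(m$subjects), function(id)
    read_subject(file.path(base, id, "manifest.json")))
  names(subjects) <- names(m$subjects)
  subjects
}

#' Persist / restore a trained detector bundle
#'
#' Both boosters are written in the native xgboost serialisation with a
#' JSON sidecar recording the feature schemas, hyperparameters,
#' configuration hash and seed.
#'
#' @param bundle a `detector_bundle` from [train_detector].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_detector <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(bundle$c1$booster, file.path(dir, "c1.ubj"))
  xgboost::xgb.save(bundle$c2$booster, file.path(dir, "c2.ubj"))
  side <- list(c1_features = bundle$c1$feature_cols,
               c2_features = bundle$c2$feature_cols,
               c1_params = bundle$c1$params,
               c2_params = bundle$c2$params,
               config = unclass(bundle$config), seed = bundle$seed,
               config_hash = config_hash(unclass(bundle$config)))
  jsonlite::write_json(side, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname save_detector
#' @export
load_detector <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  cfg <- side$config
  config <- detector_config(
    c1_modalities = cfg$c1_modalities, c2_volumes = cfg$c2_volumes,
    normalize = cfg$normalize,
    shell_thickness_mm = cfg$shell_thickness_mm, ratio = cfg$ratio,
    control_quota = cfg$control_quota, threshold = cfg$threshold,
    c1 = cfg$c1, c2 = cfg$c2)
  c1 <- structure(list(booster = xgboost::xgb.load(file.path(dir,
                                                             "c1.ubj")),
                       feature_cols = side$c1_features,
                       params = side$c1_params, seed = side$seed),
                  class = "c1_model")
  c2 <- structure(list(booster = xgboost::xgb.load(file.path(dir,
                                                             "c2.ubj")),
                       feature_cols = side$c2_features,
                       params = side$c2_params, seed = side$seed),
                  class = "c2_model")
  structure(list(c1 = c1, c2 = c2, config = config, seed = side$seed),
            class = "detector_bundle")
}

#' Write an abnormality map as NIfTI (probabilities + binary mask)
#' @param map an [abnormality_map].
#' @param prefix output path prefix; writes `<prefix>_prob.nii.gz` and
#'   `<prefix>_mask.nii.gz`.
#' @return the two paths, invisibly.
#' @export
write_abnormality_map <- function(map, prefix) {
  pp <- paste0(prefix, "_prob.nii.gz")
  mp <- paste0(prefix, "_mask.nii.gz")
  write_volume(map$probabilities, pp)
  g <- map$probabilities
  write_volume(volume_grid(array(as.integer(map$binary),
                                 dim = dim(map$binary)),
                           g$spacing, g$affine, "binary"), mp,
               datatype = "uint8")
  invisible(c(probabilities = pp, mask = mp))
}
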