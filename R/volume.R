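#' A 3-D scalar image with voxel spacing and a voxel-to-world affine
#'
#' `volume_grid` is the unit of all imaging I/O in lesionstack: a plain 3-D
#' array together with its voxel spacing in mm and a 4x4 affine mapping
#' 0-based voxel indices to world coordinates (RAS, mm). All geometry-aware
#' operations (boundary shells, electrode-contact distances) work in world
#' mm through the affine, so anisotropic voxels are handled throughout.
#'
#' @param data a 3-D numeric or integer array.
#' @param spacing voxel spacing `c(sx, sy, sz)` in mm, all positive.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, RAS mm).
#'   Defaults to a diagonal affine built from `spacing` with the origin at
#'   voxel (0, 0, 0).
#' @param modality free-text modality tag (e.g. `"t1"`, `"flair"`).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        modality = "") {
  if (length(dim(data)) != 3L)
    stop("volume_grid requires a 3-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values", call. = FALSE)
  if (is.null(affine))
    affine <- rbind(cbind(diag(spacing), c(0, 0, 0)), c(0, 0, 0, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det(affine)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, spacing = spacing, affine = affine,
                 modality = as.character(modality)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm", if (nzchar(x$modality)) paste0(", modality '", x$modality, "'"),
      "\n", sep = "")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a [volume_grid], taking spacing and the
#' voxel-to-world affine from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach; defaults to the file base name.
#' @return A [volume_grid].
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  spacing <- RNifti::pixdim(img)
  if (any(spacing <= 0))
    stop("degenerate voxel spacing in header of ", path, call. = FALSE)
  if (is.null(modality))
    modality <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_grid(array(as.numeric(img), dim = d), spacing = spacing,
              affine = matrix(as.numeric(RNifti::xform(img)), 4L, 4L),
              modality = modality)
}

#' Write a volume_grid as NIfTI
#'
#' @param volume a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype: `"double"` (default) keeps lattice
#'   values bit-exact; use `"uint8"` for masks or `"float"`/`"int16"` to
#'   save space.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  sf <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- sf
  RNifti::qform(img) <- sf
  img <- RNifti::asNifti(img)  # rebuild the internal header
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

#' Map voxel indices to world coordinates
#'
#' @param idx n x 3 matrix of 1-based voxel indices (R array convention).
#' @param affine 4x4 voxel-to-world matrix over 0-based indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(idx, affine) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional) 1-based voxel indices
#' @param xyz n x 3 matrix of world mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE] + 1
}

# coerce masks/arrays/volume_grids to a plain logical array
as_mask_array <- function(x) {
  if (inherits(x, "volume_grid")) x <- x$data
  if (inherits(x, "parcellation_map")) x <- x$labels > 0
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a 3-D lattice", call. = FALSE)
  array(x != 0, dim = dim(x))
}

#' An integer brain parcellation sharing geometry with its study
#'
#' @param labels 3-D integer array; 0 is background, positive values are
#'   region identifiers.
#' @param spacing,affine geometry, as for [volume_grid].
#' @param region_names optional named character vector (id -> name).
#' @return An object of class `parcellation_map` with a sorted `region_ids`
#'   field.
#' @export
parcellation_map <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                             region_names = NULL) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("negative parcellation labels are not allowed", call. = FALSE)
  g <- volume_grid(labels, spacing = spacing, affine = affine,
                   modality = "parcellation")
  structure(list(labels = labels, spacing = g$spacing, affine = g$affine,
                 region_ids = sort(unique(labels[labels > 0L])),
                 region_names = region_names),
            class = "parcellation_map")
}

#' Brain mask of a parcellation: the union of all labelled regions
#' @param parcellation a [parcellation_map].
#' @return logical 3-D array.
#' @export
brain_mask <- function(parcellation) {
  parcellation$labels > 0L
}

#' A co-registered multimodal study for one subject
#'
#' Bundles the modality volumes, parcellation, cortical-thickness map and
#' (optionally) a binary lesion mask for one subject. All members must share
#' shape, spacing and affine. Positives must carry a nonempty lesion mask;
#' controls an empty (or absent, treated as empty) one.
#'
#' @param subject_id subject identifier.
#' @param group one of `"control"`, `"mri_positive"`, `"mri_negative"`.
#' @param volumes named list of [volume_grid]s, keyed by modality tag.
#' @param parcellation a [parcellation_map].
#' @param cortical_thickness a [volume_grid] (mm).
#' @param lesion_mask binary 3-D array or NULL.
#' @return An object of class `subject_study`.
#' @export
subject_study <- function(subject_id, group, volumes, parcellation,
                          cortical_thickness, lesion_mask = NULL) {
  group <- match.arg(group, c("control", "mri_positive", "mri_negative"))
  if (length(volumes) == 0L)
    stop("at least one modality volume is required", call. = FALSE)
  ref <- volumes[[1L]]
  pg <- volume_grid(parcellation$labels, parcellation$spacing,
                    parcellation$affine)
  for (v in c(volumes, list(pg, cortical_thickness)))
    if (!same_geometry(ref, v))
      stop("all member grids of a subject must share geometry",
           call. = FALSE)
  if (is.null(lesion_mask))
    lesion_mask <- array(0L, dim = dim(ref$data))
  lesion_mask <- as_mask_array(lesion_mask)
  if (!all(dim(lesion_mask) == dim(ref$data)))
    stop("lesion mask geometry mismatch", call. = FALSE)
  n_les <- sum(lesion_mask)
  if (group == "mri_positive" && n_les == 0L)
    stop("an mri_positive subject requires a nonempty lesion mask",
         call. = FALSE)
  if (group == "control" && n_les > 0L)
    stop("a control subject must have an empty lesion mask", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), group = group,
                 volumes = volumes, parcellation = parcellation,
                 cortical_thickness = cortical_thickness,
                 lesion_mask = lesion_mask),
            class = "subject_study")
}

#' @export
print.subject_study <- function(x, ...) {
  cat("<subject_study> ", x$subject_id, " (", x$group, "), ",
      length(x$volumes), " modalities [",
      paste(names(x$volumes), collapse = ", "), "], ",
      sum(x$lesion_mask), " lesion voxels\n", sep = "")
  invisible(x)
}

#' A voxelwise probabilistic abnormality map with a binary threshold
#'
#' @param probabilities [volume_grid] of per-voxel abnormality
#'   probabilities in `[0, 1]` (0 outside the brain).
#' @param threshold binarisation threshold in `(0, 1]`.
#' @return An object of class `abnormality_map` whose `binary` field is
#'   `probabilities >= threshold`.
#' @export
abnormality_map <- function(probabilities, threshold = 0.5) {
  stopifnot(inherits(probabilities, "volume_grid"))
  p <- probabilities$data
  if (any(p < -1e-9 | p > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]", call. = FALSE)
  structure(list(probabilities = probabilities, threshold = threshold,
                 binary = p >= threshold),
            class = "abnormality_map")
}

#' @export
print.abnormality_map <- function(x, ...) {
  cat("<abnormality_map> ", sum(x$binary), " voxels above threshold ",
      x$threshold, " (max p = ", signif(max(x$probabilities$data), 3),
      ")\n", sep = "")
  invisible(x)
}
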