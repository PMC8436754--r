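#' Z-score a structural contrast over in-mask voxels
#'
#' Raw structural contrasts (T1, FLAIR, SWI) carry arbitrary scanner units
#' and are standardised to zero mean and unit standard deviation over the
#' brain mask before feature extraction; quantitative maps (diffusion
#' metrics, NODDI NDI, DESPOT, cortical thickness) are already in physical
#' units and are left untouched by the pipeline configuration. The standard
#' deviation uses the n (population) divisor. Out-of-mask voxels are set
#' to 0.
#'
#' @param volume a [volume_grid].
#' @param mask binary 3-D lattice (array, [volume_grid] or
#'   [parcellation_map]) marking the brain; must be nonempty.
#' @return A [volume_grid] with in-mask mean 0 and SD 1.
#' @export
normalize_intensities <- function(volume, mask) {
  stopifnot(inherits(volume, "volume_grid"))
  m <- as_mask_array(mask)
  if (!all(dim(m) == dim(volume$data)))
    stop("mask geometry mismatch", call. = FALSE)
  if (!any(m))
    stop("brain mask is empty", call. = FALSE)
  v <- volume$data[m]
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev < 1e-12)
    stop("zero in-mask variance: cannot normalize a constant image",
         call. = FALSE)
  out <- volume
  z <- array(0, dim = dim(volume$data))
  z[m] <- (v - mu) / sdev
  out$data <- z
  out
}

#' Dice similarity coefficient between two binary masks
#'
#' DSC = 2|A intersect B| / (|A| + |B|), the standard spatial-overlap
#' metric for segmentation evaluation. Two empty masks agree perfectly on
#' "nothing" and score 1, which keeps control-subject evaluation
#' well-defined.
#'
#' @param a,b binary 3-D lattices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask_array(a)
  b <- as_mask_array(b)
  if (!all(dim(a) == dim(b)))
    stop("mask shapes differ", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Voxelwise sensitivity and specificity over a domain mask
#'
#' Confusion-matrix counting restricted to `domain_mask` voxels (the brain
#' mask by convention: including air voxels would inflate specificity
#' meaninglessly). With an empty truth mask sensitivity is undefined and
#' reported as `NaN` with a warning.
#'
#' @param pred,truth binary 3-D lattices.
#' @param domain_mask binary 3-D lattice restricting the counted voxels.
#' @return named numeric `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(pred, truth, domain_mask) {
  pred <- as_mask_array(pred)
  truth <- as_mask_array(truth)
  domain <- as_mask_array(domain_mask)
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(domain)))
    stop("lattice shapes differ", call. = FALSE)
  p <- pred[domain]
  t <- truth[domain]
  tp <- sum(p & t); fn <- sum(!p & t)
  tn <- sum(!p & !t); fp <- sum(p & !t)
  if (tp + fn == 0L) {
    warning("empty truth mask: sensitivity undefined")
    sens <- NaN
  } else sens <- tp / (tp + fn)
  spec <- if (tn + fp == 0L) NaN else tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}
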