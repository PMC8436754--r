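# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures))
    assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small cohort: 32^3 lattice, 12 regions, 4 positives + 3 controls
small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(phantom_config(lattice_shape = c(32, 32, 32),
                                   n_regions = 12, n_positives = 4,
                                   n_controls = 3,
                                   lesion_radius_mm = c(3, 5),
                                   seed = 7))
  })
}

# a bundle trained on the small cohort with light hyperparameters
small_bundle <- function() {
  memo("small_bundle", function() {
    train_detector(small_cohort()$subjects,
                   detector_config(control_quota = 300,
                                   c2 = c2_params(nrounds = 60)),
                   seed = 1)
  })
}

fast_config <- function(...) {
  detector_config(control_quota = 300,
                  c1 = c1_params(nrounds = 80),
                  c2 = c2_params(nrounds = 60), ...)
}

# a hand-built two-region parcellation: region 1 is a cuboid, region 2
# the rest of a full-lattice "brain"
cuboid_parcellation <- function(shape = c(9, 9, 9),
                                lo = c(3, 3, 3), hi = c(7, 7, 7),
                                spacing = c(1, 1, 1)) {
  labels <- array(2L, dim = shape)
  labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  parcellation_map(labels, spacing = spacing)
}

# a subject with given constant / supplied modality arrays over a
# parcellation (for feature-extraction contracts)
toy_subject <- function(parcellation, arrays, lesion = NULL,
                        group = NULL, thickness = NULL) {
  shape <- dim(parcellation$labels)
  vols <- lapply(names(arrays), function(tag) {
    a <- arrays[[tag]]
    if (length(a) == 1L) a <- array(a, dim = shape)
    volume_grid(a, parcellation$spacing, parcellation$affine, tag)
  })
  names(vols) <- names(arrays)
  if (is.null(thickness))
    thickness <- volume_grid(array(2.5, dim = shape),
                             parcellation$spacing, parcellation$affine,
                             "thickness")
  if (is.null(group))
    group <- if (is.null(lesion) || sum(lesion) == 0) "control"
             else "mri_positive"
  subject_study("toy", group, vols, parcellation, thickness,
                lesion_mask = lesion)
}

## ---- independent oracles -------------------------------------------

# brute-force Dice by explicit per-voxel counting; shares no set algebra
# with the implementation
dice_oracle <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1L
    if (b[i]) nb <- nb + 1L
    if (a[i] && b[i]) inter <- inter + 1L
  }
  if (na + nb == 0L) return(1)
  2 * inter / (na + nb)
}

# exhaustive per-voxel min-distance shells (no distance transform)
shells_oracle <- function(parcellation, region_id, thickness_mm = 1.0) {
  labels <- parcellation$labels
  sp <- parcellation$spacing
  region <- labels == region_id
  brain <- labels > 0L
  idx_all <- which(array(TRUE, dim(labels)), arr.ind = TRUE)
  mm <- sweep(idx_all - 1, 2, sp, `*`)
  reg_mm <- mm[region, , drop = FALSE]
  out_mm <- mm[!region, , drop = FALSE]
  min_d <- function(points, targets) {
    vapply(seq_len(nrow(points)), function(r)
      sqrt(min(colSums((t(targets) - points[r, ])^2))), numeric(1))
  }
  d_out <- array(0, dim(labels))
  d_out[region] <- min_d(reg_mm, out_mm)
  d_reg <- array(0, dim(labels))
  d_reg[!region] <- min_d(out_mm, reg_mm)
  core <- region & d_out > thickness_mm
  list(core = core,
       inner_shell = region & !core,
       outer_shell = brain & !region & d_reg <= thickness_mm)
}

# exact two-tailed Mann-Whitney p by enumeration of group assignments,
# with U computed by direct pair counting (not the rank-sum identity)
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yj in ys)
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  u_obs <- u_of(x, y)
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix)
    u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
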