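# Per-modality intensity profiles for the phantom generator. Structural
# contrasts use arbitrary scanner-like units; quantitative maps use
# plausible physical values (diffusivities in um^2/ms, NDI/FA unitless).
# "distractor" is a pure-noise channel (no regional structure, never
# lesion-affected) for ablation experiments.
phantom_modality_profiles <- function() {
  data.frame(
    modality  = c("t1", "flair", "swi", "ndi", "ad", "fa", "rd",
                  "despot_t1", "despot_pd", "distractor"),
    base_mean = c(100, 90, 80, 0.5, 1.2, 0.4, 0.7, 1200, 80, 0),
    region_sd = c(10, 10, 8, 0.05, 0.10, 0.05, 0.08, 100, 8, 0),
    noise_sd  = c(5, 5, 4, 0.03, 0.06, 0.03, 0.04, 60, 5, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic multimodal cohort
#'
#' Defines the study conditions a phantom cohort is generated under:
#' lattice geometry, number of parcellated regions, modality list,
#' cohort sizes, lesion geometry and the lesion effect size expressed in
#' units of the within-region noise standard deviation of each affected
#' modality.
#'
#' @param lattice_shape integer 3-vector of lattice dimensions.
#' @param spacing voxel spacing in mm.
#' @param n_regions number of parcellated regions (>= 2; 157 mirrors a
#'   whole-brain anatomical parcellation, 27 is the desk-scale default).
#' @param modalities character vector of modality tags to synthesise.
#' @param n_positives,n_controls cohort sizes.
#' @param lesion_radius_mm length-2 range the mean lesion semi-axis is
#'   drawn from, in mm.
#' @param affected_modalities subset of `modalities` whose intensity the
#'   lesion shifts.
#' @param effect_size_sd lesion intensity shift in units of the affected
#'   modality's noise SD (>= 0).
#' @param lesion_style `"focal"` plants an axis-aligned ellipsoid centred
#'   inside a randomly chosen region (it may straddle region boundaries);
#'   `"region"` marks one entire region as lesional.
#' @param noise_sd optional named numeric vector overriding per-modality
#'   noise SDs.
#' @param seed integer seed; mandatory — phantom cohorts are fully
#'   deterministic given their configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(lattice_shape = c(48, 48, 48),
                           spacing = c(1, 1, 1),
                           n_regions = 27,
                           modalities = c("t1", "flair", "ndi", "ad",
                                          "fa", "rd"),
                           n_positives = 20, n_controls = 20,
                           lesion_radius_mm = c(4, 7),
                           affected_modalities = c("flair", "ndi"),
                           effect_size_sd = 3,
                           lesion_style = c("focal", "region"),
                           noise_sd = NULL,
                           seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for phantom generation", call. = FALSE)
  lesion_style <- match.arg(lesion_style)
  if (n_regions < 2)
    stop("n_regions must be at least 2", call. = FALSE)
  if (effect_size_sd < 0)
    stop("effect_size_sd must be nonnegative", call. = FALSE)
  lesion_radius_mm <- sort(as.numeric(lesion_radius_mm))
  if (lesion_radius_mm[1] < max(spacing))
    stop("lesion radius must span at least one voxel in every axis",
         call. = FALSE)
  if (!all(affected_modalities %in% modalities))
    stop("affected_modalities must be a subset of modalities",
         call. = FALSE)
  prof <- phantom_modality_profiles()
  ns <- setNames(rep(1, length(modalities)), modalities)
  known <- intersect(modalities, prof$modality)
  ns[known] <- prof$noise_sd[match(known, prof$modality)]
  if (!is.null(noise_sd)) ns[names(noise_sd)] <- noise_sd
  structure(list(lattice_shape = as.integer(lattice_shape),
                 spacing = as.numeric(spacing),
                 n_regions = as.integer(n_regions),
                 modalities = modalities,
                 n_positives = as.integer(n_positives),
                 n_controls = as.integer(n_controls),
                 lesion_radius_mm = lesion_radius_mm,
                 affected_modalities = affected_modalities,
                 effect_size_sd = effect_size_sd,
                 lesion_style = lesion_style,
                 noise_sd = ns,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# voxel-centre coordinates in mm along each axis (grid distances; phantom
# affines are axis-aligned so these equal world offsets)
axis_mm <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# smooth a 3-D array with a separable 5-tap binomial kernel, edge-clamped
smooth3 <- function(arr, passes = 2L) {
  w <- c(1, 4, 6, 4, 1) / 16
  shift_axis <- function(x, axis, by) {
    n <- dim(x)[axis]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
  for (p in seq_len(passes))
    for (axis in 1:3) {
      acc <- array(0, dim(arr))
      for (k in -2:2) acc <- acc + w[k + 3] * shift_axis(arr, axis, k)
      arr <- acc
    }
  arr
}

#' Generate a synthetic brain parcellation
#'
#' Partitions an inscribed ellipsoidal "brain" into `n_regions` contiguous
#' regions as the Voronoi cells (Euclidean, in mm) of seed points drawn
#' uniformly from the brain; label 0 marks background. Cells of a Voronoi
#' diagram intersected with the convex brain are convex, hence contiguous.
#' Regeneration with the same configuration yields an identical lattice.
#'
#' @param config a [phantom_config].
#' @param reseed reinitialise the RNG from `config$seed` (default); set
#'   `FALSE` to draw from the current RNG stream (used internally by
#'   [simulate_cohort]).
#' @param min_region_voxels smallest admissible region (default 27); the
#'   seed points are redrawn, up to 50 times, until every region clears it.
#' @return A [parcellation_map].
#' @export
make_parcellation <- function(config, reseed = TRUE,
                              min_region_voxels = 27L) {
  stopifnot(inherits(config, "phantom_config"))
  if (reseed) set.seed(config$seed)
  shape <- config$lattice_shape
  sp <- config$spacing
  ax <- axis_mm(shape, sp)
  centre <- vapply(ax, function(v) mean(range(v)), numeric(1))
  semi <- vapply(ax, function(v) diff(range(v)) / 2, numeric(1)) * 0.92
  gx <- (ax[[1]] - centre[1]) / semi[1]
  gy <- (ax[[2]] - centre[2]) / semi[2]
  gz <- (ax[[3]] - centre[3]) / semi[3]
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  brain <- r2 <= 1
  n_brain <- sum(brain)
  if (n_brain < config$n_regions * min_region_voxels)
    stop("lattice too small for ", config$n_regions, " regions of >= ",
         min_region_voxels, " voxels", call. = FALSE)
  vox <- which(brain, arr.ind = TRUE)
  mm <- sweep(vox - 1, 2, sp, `*`)
  for (attempt in 1:50) {
    pick <- sample.int(n_brain, config$n_regions)
    seeds <- mm[pick, , drop = FALSE]
    # squared distance of every brain voxel to every seed
    d2 <- outer(rowSums(mm^2), rep(1, config$n_regions)) -
      2 * (mm %*% t(seeds)) +
      outer(rep(1, n_brain), rowSums(seeds^2))
    lab_vec <- max.col(-d2, ties.method = "first")
    counts <- tabulate(lab_vec, nbins = config$n_regions)
    if (min(counts) >= min_region_voxels) {
      labels <- array(0L, dim = shape)
      labels[brain] <- lab_vec
      return(parcellation_map(labels, spacing = sp))
    }
  }
  stop("could not draw a parcellation with every region >= ",
       min_region_voxels, " voxels; reduce n_regions", call. = FALSE)
}

# draw one ellipsoidal lesion mask fully inside the brain, centred in
# a randomly chosen region; returns list(mask, centre_mm, semi_mm, region)
plant_lesion <- function(config, parcellation, brain) {
  shape <- config$lattice_shape
  sp <- config$spacing
  ax <- axis_mm(shape, sp)
  for (attempt in 1:25) {
    region <- sample(parcellation$region_ids, 1)
    rv <- which(parcellation$labels == region, arr.ind = TRUE)
    c_vox <- rv[sample.int(nrow(rv), 1), ]
    centre <- (c_vox - 1) * sp
    r <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    semi <- pmax(r * runif(3, 0.85, 1.2), sp)
    ex <- (ax[[1]] - centre[1]) / semi[1]
    ey <- (ax[[2]] - centre[2]) / semi[2]
    ez <- (ax[[3]] - centre[3]) / semi[3]
    mask <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`) <= 1
    if (sum(mask) > 0 && all(brain[mask]))
      return(list(mask = mask, centre_mm = centre, semi_mm = semi,
                  region = region))
  }
  stop("failed to place a lesion inside the brain after 25 attempts",
       call. = FALSE)
}

#' Synthesise one subject of a phantom cohort
#'
#' Each modality is the per-region mean (shared across the cohort, so the
#' regional detector can learn region-specific normal appearance) plus
#' white Gaussian noise; cortical thickness is a smooth positive field
#' around 2.5 mm. A positive subject carries a planted lesion that shifts
#' each affected modality by `effect_size_sd` times its noise SD and is
#' recorded in the lesion mask; controls carry empty masks.
#'
#' Draws from the current RNG stream; pass `seed` for standalone
#' deterministic use.
#'
#' @param config a [phantom_config].
#' @param parcellation a [parcellation_map] from [make_parcellation].
#' @param region_means matrix (n_regions x modalities) of per-region mean
#'   intensities; see [draw_region_means].
#' @param is_positive plant a lesion?
#' @param subject_id subject identifier.
#' @param lesion_region for `lesion_style = "region"`, the region id to
#'   mark lesional; NULL draws one at random.
#' @param seed optional integer to reinitialise the RNG first.
#' @return A [subject_study]; lesion ground truth (centre, semi-axes,
#'   region, affected modalities) is attached as attribute `"truth"` for
#'   positives.
#' @export
synthesize_subject <- function(config, parcellation, region_means,
                               is_positive, subject_id = "subj",
                               lesion_region = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape <- config$lattice_shape
  sp <- config$spacing
  brain <- brain_mask(parcellation)
  lab <- parcellation$labels
  n_brain <- sum(brain)

  truth <- NULL
  lesion <- array(FALSE, dim = shape)
  if (is_positive) {
    if (config$lesion_style == "region") {
      region <- if (is.null(lesion_region)) sample(parcellation$region_ids, 1)
                else lesion_region
      lesion <- lab == region
      rv <- which(lesion, arr.ind = TRUE)
      truth <- list(centre_mm = colMeans(sweep(rv - 1, 2, sp, `*`)),
                    semi_mm = NA_real_, region = region,
                    affected = config$affected_modalities)
    } else {
      pl <- plant_lesion(config, parcellation, brain)
      lesion <- pl$mask
      truth <- list(centre_mm = pl$centre_mm, semi_mm = pl$semi_mm,
                    region = pl$region,
                    affected = config$affected_modalities)
    }
  }

  volumes <- vector("list", length(config$modalities))
  names(volumes) <- config$modalities
  for (mod in config$modalities) {
    arr <- array(0, dim = shape)
    mu <- region_means[, mod][lab[brain]]
    arr[brain] <- mu + rnorm(n_brain, sd = config$noise_sd[[mod]])
    if (is_positive && mod %in% config$affected_modalities)
      arr[lesion] <- arr[lesion] +
        config$effect_size_sd * config$noise_sd[[mod]]
    volumes[[mod]] <- volume_grid(arr, spacing = sp, modality = mod)
  }

  field <- smooth3(array(rnorm(prod(shape)), dim = shape))
  sfield <- field[brain]
  sfield <- (sfield - mean(sfield)) / max(sd(sfield), 1e-12)
  thick <- array(0, dim = shape)
  thick[brain] <- pmax(2.5 + 0.4 * sfield, 0.5)
  thickness <- volume_grid(thick, spacing = sp, modality = "thickness")

  subj <- subject_study(subject_id,
                        group = if (is_positive) "mri_positive"
                                else "control",
                        volumes = volumes, parcellation = parcellation,
                        cortical_thickness = thickness,
                        lesion_mask = lesion)
  attr(subj, "truth") <- truth
  subj
}

#' Draw the cohort-shared per-region mean intensities
#'
#' One mean per (region, modality), drawn from the modality's base level
#' and between-region SD; shared across all subjects of a cohort so that
#' region-specific normal appearance is a learnable signal.
#'
#' @param config a [phantom_config].
#' @return matrix `n_regions x length(modalities)` with modality columns.
#' @export
draw_region_means <- function(config) {
  prof <- phantom_modality_profiles()
  m <- sapply(config$modalities, function(mod) {
    i <- match(mod, prof$modality)
    base <- if (is.na(i)) 0 else prof$base_mean[i]
    rsd <- if (is.na(i)) 1 else prof$region_sd[i]
    base + rnorm(config$n_regions, sd = rsd)
  })
  matrix(m, nrow = config$n_regions,
         dimnames = list(NULL, config$modalities))
}

#' Simulate a full phantom cohort
#'
#' Generates the shared parcellation, the cohort-level region means and
#' `n_positives + n_controls` subjects, all deterministically from
#' `config$seed`. For `lesion_style = "region"` the lesional regions are
#' assigned to positives round-robin, so every region recurs among the
#' lesional examples as evenly as the cohort size allows (the balanced
#' coverage the regional stage needs to learn region-conditioned normal
#' appearance).
#'
#' @param config a [phantom_config].
#' @return An object of class `phantom_cohort`: list with `subjects`
#'   (positives first, ids `pos01..`, `ctl01..`), `parcellation`, `truth`
#'   (per-positive lesion metadata) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  parcellation <- make_parcellation(config, reseed = FALSE)
  region_means <- draw_region_means(config)
  n <- config$n_positives + config$n_controls
  ids <- c(sprintf("pos%02d", seq_len(config$n_positives)),
           sprintf("ctl%02d", seq_len(config$n_controls)))
  subjects <- vector("list", n)
  truth <- vector("list", n)
  cycle <- parcellation$region_ids[
    (seq_len(config$n_positives) - 1L) %% config$n_regions + 1L]
  for (s in seq_len(n)) {
    is_pos <- s <= config$n_positives
    reg <- if (is_pos && config$lesion_style == "region") cycle[s]
           else NULL
    subjects[[s]] <- synthesize_subject(config, parcellation,
                                        region_means, is_pos, ids[s],
                                        lesion_region = reg)
    truth[s] <- list(attr(subjects[[s]], "truth"))
  }
  names(subjects) <- ids
  names(truth) <- ids
  structure(list(subjects = subjects, parcellation = parcellation,
                 truth = truth, region_means = region_means,
                 config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", x$config$n_positives, " positives + ",
      x$config$n_controls, " controls, ",
      paste(x$config$lattice_shape, collapse = "x"), " lattice, ",
      x$config$n_regions, " regions, effect ",
      x$config$effect_size_sd, " SD in [",
      paste(x$config$affected_modalities, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Place synthetic SEEG contacts for a subject
#'
#' Builds a small contact table in world mm for one of three scenarios:
#' `onset_in_lesion` puts the seizure-onset contact at the lesion centroid
#' (with propagation ~8 mm and interictal ~15 mm away and one silent
#' contact far from the lesion); `onset_far` puts the onset contact more
#' than 25 mm from every lesion voxel while propagation samples the
#' lesion; `mixed` provides one contact of every role plus a silent one.
#' All scenarios require a subject with a nonempty lesion mask.
#'
#' @param subject a [subject_study] with a nonempty lesion mask.
#' @param scenario one of `"onset_in_lesion"`, `"onset_far"`, `"mixed"`.
#' @return data.frame with columns `contact_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `onset`, `propagation`, `interictal` (0/1 flags).
#' @export
make_contacts <- function(subject,
                          scenario = c("onset_in_lesion", "onset_far",
                                       "mixed")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(subject, "subject_study"))
  lesion <- subject$lesion_mask
  if (!any(lesion))
    stop("scenario '", scenario,
         "' requires a subject with a lesion; got an empty mask",
         call. = FALSE)
  sp <- subject$parcellation$spacing
  aff <- subject$parcellation$affine
  brain <- brain_mask(subject$parcellation)
  d_les <- distance_to_set(lesion, sp)

  lesion_centre <- function() {
    lv <- which(lesion, arr.ind = TRUE)
    cen <- colMeans(lv)
    i <- which.min(rowSums(sweep(sweep(lv, 2, cen), 2, sp, `*`)^2))
    voxel_to_world(lv[i, , drop = FALSE], aff)
  }
  at_distance <- function(lo, hi, target) {
    cand <- which(brain & d_les >= lo & d_les <= hi)
    if (length(cand) == 0L)
      stop("no brain voxel at ", lo, "-", hi, " mm from the lesion",
           call. = FALSE)
    i <- cand[which.min(abs(d_les[cand] - target))]
    voxel_to_world(which_vox(i, dim(lesion)), aff)
  }
  far_voxel <- function(min_mm) {
    cand <- which(brain & d_les > min_mm)
    if (length(cand) == 0L)
      stop("no brain voxel farther than ", min_mm,
           " mm from the lesion", call. = FALSE)
    i <- cand[which.max(d_les[cand])]
    voxel_to_world(which_vox(i, dim(lesion)), aff)
  }

  row <- function(id, xyz, onset = 0, propagation = 0, interictal = 0)
    data.frame(contact_id = id, x_mm = xyz[1], y_mm = xyz[2],
               z_mm = xyz[3], onset = onset, propagation = propagation,
               interictal = interictal, stringsAsFactors = FALSE)

  tab <- switch(scenario,
    onset_in_lesion = rbind(
      row("A1", lesion_centre(), onset = 1),
      row("A2", at_distance(5, 11, 8), propagation = 1),
      row("A3", at_distance(11, 22, 15), interictal = 1),
      row("A4", far_voxel(12))),
    onset_far = rbind(
      row("B1", far_voxel(25), onset = 1),
      row("B2", lesion_centre(), propagation = 1),
      row("B3", at_distance(5, 12, 8), interictal = 1)),
    mixed = rbind(
      row("C1", lesion_centre(), onset = 1),
      row("C2", at_distance(5, 11, 8), propagation = 1),
      row("C3", at_distance(11, 22, 15), interictal = 1),
      row("C4", far_voxel(12))))
  rownames(tab) <- NULL
  tab
}

# linear index -> 1-based (i, j, k) matrix row
which_vox <- function(lin, dims) {
  matrix(arrayInd(lin, dims), ncol = 3L)
}
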