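test_that("lesion_fraction maps coverage to the exact fraction", {
  # region 1: a 10-voxel strip; lesion covers exactly one voxel -> 0.1
  labels <- array(2L, c(10, 3, 3))
  labels[1:10, 1, 1] <- 1L
  parc <- parcellation_map(labels)
  mask <- array(0L, c(10, 3, 3)); mask[1, 1, 1] <- 1L
  expect_identical(lesion_fraction(parc, 1L, mask), 0.1)
  expect_identical(lesion_fraction(parc, 1L, array(0L, c(10, 3, 3))), 0)
  full <- array(0L, c(10, 3, 3)); full[1:10, 1, 1] <- 1L
  expect_identical(lesion_fraction(parc, 1L, full), 1)
  expect_error(lesion_fraction(parc, 9L, mask), "empty")
})

test_that("region-weighted lesion fractions conserve total lesion volume", {
  coh <- small_cohort()
  parc <- coh$parcellation
  brain_n <- sum(brain_mask(parc))
  for (s in coh$subjects[1:4]) {
    fr <- vapply(parc$region_ids, function(id)
      lesion_fraction(parc, id, s$lesion_mask), numeric(1))
    sizes <- vapply(parc$region_ids, function(id)
      sum(parc$labels == id), numeric(1))
    expect_equal(sum(fr * sizes) / brain_n,
                 sum(s$lesion_mask) / brain_n)
  }
})

test_that("regional feature schema: 1 + 6M columns, deterministic order", {
  parc <- cuboid_parcellation(c(9, 9, 9), c(3, 3, 3), c(7, 7, 7))
  s <- toy_subject(parc, list(t1 = 7, flair = 3))
  sh <- extract_shells(parc, 1L)
  f <- regional_features(s, 1L, sh)
  expect_length(f, 1 + 6 * 2)
  expect_equal(names(f)[1], "normalized_volume")
  # constant modalities: mean = constant, sd = 0 in every compartment
  expect_equal(unname(f["t1_core_mean"]), 7)
  expect_equal(unname(f["t1_outer_sd"]), 0)
  expect_equal(unname(f["flair_inner_mean"]), 3)
  # region occupies 125 of 729 voxels
  expect_equal(unname(f["normalized_volume"]), 125 / 729)
  # a 9-modality subject yields the 55-column schema
  mods <- setNames(as.list(1:9), c("t1", "flair", "swi", "ndi", "ad",
                                   "fa", "rd", "despot_t1", "despot_pd"))
  s9 <- toy_subject(parc, mods)
  expect_length(regional_features(s9, 1L, sh), 55)
})

test_that("normalized volume is the region share of the brain", {
  labels <- array(2L, c(10, 10, 10))
  labels[1:10, 1:10, 1] <- 1L  # 100 of 1000 voxels
  parc <- parcellation_map(labels)
  s <- toy_subject(parc, list(t1 = 1))
  f <- regional_features(s, 1L, extract_shells(parc, 1L))
  expect_equal(unname(f["normalized_volume"]), 0.1)
})

test_that("empty compartments fall back to parent-region statistics", {
  labels <- array(2L, c(7, 7, 7))
  labels[4, 4, 4] <- 1L  # single-voxel region: 1 mm erosion empties core
  parc <- parcellation_map(labels)
  set.seed(1)
  s <- toy_subject(parc, list(t1 = array(rnorm(343, 5), c(7, 7, 7))))
  sh <- extract_shells(parc, 1L)
  f <- regional_features(s, 1L, sh)
  expect_true(attr(f, "empty_compartment"))
  # core stats substituted by the (single-voxel) parent region
  expect_equal(unname(f["t1_core_mean"]), s$volumes$t1$data[4, 4, 4])
  expect_equal(unname(f["t1_core_sd"]), 0)
  tab <- build_regional_table(list(s))
  expect_false(anyNA(tab))
  expect_true(tab$empty_compartment[tab$region_id == 1])
})

test_that("the regional regressor separates shifted regions and is
          deterministic", {
  # synthetic feature table: 60 normal rows, 20 rows with a 3-SD shift
  set.seed(17)
  make_rows <- function(n, shift) {
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    X[, 2] <- X[, 2] + shift
    X
  }
  train <- rbind(
    data.frame(subject_id = "a", region_id = 1:60, lesion_fraction = 0,
               empty_compartment = FALSE, make_rows(60, 0)),
    data.frame(subject_id = "b", region_id = 1:20, lesion_fraction = 0.5,
               empty_compartment = FALSE, make_rows(20, 3)))
  m1 <- train_c1(train, c1_params(nrounds = 60), seed = 4)
  m2 <- train_c1(train, c1_params(nrounds = 60), seed = 4)
  held_norm <- data.frame(subject_id = "h", region_id = 1:30,
                          lesion_fraction = 0, empty_compartment = FALSE,
                          make_rows(30, 0))
  held_shift <- data.frame(subject_id = "h", region_id = 1:30,
                           lesion_fraction = 0.5,
                           empty_compartment = FALSE, make_rows(30, 3))
  p_norm <- predict_c1(m1, held_norm)
  p_shift <- predict_c1(m1, held_shift)
  expect_gt(mean(p_shift), mean(p_norm))
  expect_gt(mean(outer(p_shift, p_norm, `>`)), 0.9)
  expect_identical(predict_c1(m2, held_norm), p_norm)
  expect_true(all(p_norm >= 0 & p_norm <= 1))
  expect_true(all(p_shift >= 0 & p_shift <= 1))
  # degenerate all-zero targets refused
  allzero <- train; allzero$lesion_fraction <- 0
  expect_error(train_c1(allzero), "degenerate")
})

test_that("the rendered regional map carries one score per region", {
  coh <- small_cohort()
  b <- small_bundle()
  s <- coh$subjects$pos01
  sn <- normalize_study(s, b$config$normalize)
  rap <- predict_rap(b$c1, sn, modalities = b$config$c1_modalities)
  scores <- attr(rap, "scores")
  labs <- coh$parcellation$labels
  expect_equal(sort(unique(as.numeric(rap$data))),
               sort(unique(c(0, unname(scores)))))
  for (id in coh$parcellation$region_ids[1:4]) {
    vals <- rap$data[labs == id]
    expect_equal(unique(vals), unname(scores[as.character(id)]))
  }
  expect_true(all(rap$data[labs == 0] == 0))
})

test_that("held-out lesional regions outrank non-lesional ones", {
  # every region must recur among lesional training examples: the stage
  # learns region-conditioned normal appearance, so positives must cover
  # the parcellation several times over
  cfg <- phantom_config(lattice_shape = c(32, 32, 32), n_regions = 8,
                        n_positives = 24, n_controls = 8,
                        lesion_style = "region", effect_size_sd = 3,
                        affected_modalities = c("flair", "ndi"),
                        seed = 55)
  coh <- simulate_cohort(cfg)
  subjects <- lapply(coh$subjects, normalize_study)
  shells <- extract_all_shells(coh$parcellation)
  tab <- build_regional_table(subjects, shells = shells)
  held <- c("pos01", "pos02", "pos03")
  m <- train_c1(tab[!tab$subject_id %in% held, ],
                c1_params(nrounds = 100), seed = 2)
  ht <- tab[tab$subject_id %in% held, ]
  p <- predict_c1(m, ht)
  pos <- p[ht$lesion_fraction > 0.5]
  neg <- p[ht$lesion_fraction == 0]
  expect_gte(mean(outer(pos, neg, `>`)), 0.9)
})
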