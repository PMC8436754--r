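test_that("voxel feature schema: 7 columns per volume plus atlas label", {
  coh <- small_cohort()
  s <- coh$subjects$pos01
  zeros <- volume_grid(array(0, dim(s$lesion_mask)),
                       s$parcellation$spacing, s$parcellation$affine,
                       "rap")
  idx <- matrix(which(brain_mask(s$parcellation), arr.ind = TRUE)[1:50, ],
                ncol = 3)
  vols8 <- c("rap", "t1", "flair", "ndi", "ad", "fa", "rd", "thickness")
  vf <- voxel_features(s, zeros, idx, volumes = vols8)
  expect_equal(ncol(vf$X), 7 * 8 + 1)
  expect_equal(colnames(vf$X)[1], "rap_c")
  expect_equal(colnames(vf$X)[ncol(vf$X)], "region_label")
  expect_equal(nrow(vf$provenance), 50)
  expect_false(anyNA(vf$X))
  # labels come from the lesion mask
  expect_equal(vf$y, as.integer(s$lesion_mask[idx]))
  # atlas context equals the centre voxel's parcellation label
  expect_equal(unname(vf$X[, "region_label"]),
               as.numeric(s$parcellation$labels[idx]))
  expect_error(voxel_features(s, zeros, matrix(c(1L, 1L, 1L), 1)),
               "brain")
})

test_that("constant volumes yield constant feature columns", {
  parc <- cuboid_parcellation(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  s <- toy_subject(parc, list(t1 = 4))
  idx <- which(brain_mask(parc), arr.ind = TRUE)
  vf <- voxel_features(s, NULL, idx, volumes = c("t1", "thickness"))
  for (cc in grep("t1_", colnames(vf$X)))
    expect_true(all(vf$X[, cc] == 4))
})

test_that("edge voxels replicate the centre value into invalid slots", {
  # brain occupying the full lattice: corner voxel has 3 out-of-lattice
  # neighbours, which must equal the centre value
  labels <- array(1L, c(5, 5, 5))
  parc <- parcellation_map(labels)
  set.seed(2)
  arr <- array(rnorm(125), c(5, 5, 5))
  s <- toy_subject(parc, list(t1 = arr))
  vf <- voxel_features(s, NULL, matrix(c(1L, 1L, 1L), 1),
                       volumes = "t1")
  expect_equal(unname(vf$X[1, "t1_xm"]), arr[1, 1, 1])
  expect_equal(unname(vf$X[1, "t1_ym"]), arr[1, 1, 1])
  expect_equal(unname(vf$X[1, "t1_zm"]), arr[1, 1, 1])
  expect_equal(unname(vf$X[1, "t1_xp"]), arr[2, 1, 1])
  # out-of-brain neighbour also replicates the centre
  labels2 <- array(0L, c(5, 5, 5)); labels2[2:4, 2:4, 2:4] <- 1L
  parc2 <- parcellation_map(labels2)
  s2 <- toy_subject(parc2, list(t1 = arr))
  vf2 <- voxel_features(s2, NULL, matrix(c(2L, 3L, 3L), 1),
                        volumes = "t1")
  expect_equal(unname(vf2$X[1, "t1_xm"]), arr[2, 3, 3])  # (1,3,3) not brain
  expect_equal(unname(vf2$X[1, "t1_xp"]), arr[3, 3, 3])
})

test_that("feature extraction is translation-consistent", {
  labels <- array(0L, c(10, 10, 10)); labels[3:8, 3:8, 3:8] <- 1L
  set.seed(8)
  arr <- array(rnorm(1000), c(10, 10, 10))
  lesion <- array(0L, c(10, 10, 10)); lesion[5, 5, 5] <- 1L
  shift <- function(a) {
    out <- array(0, dim(a)); out[2:10, , ] <- a[1:9, , ]; out
  }
  s1 <- toy_subject(parcellation_map(labels), list(t1 = arr),
                    lesion = lesion)
  s2 <- toy_subject(parcellation_map(array(as.integer(shift(labels)),
                                           dim(labels))),
                    list(t1 = shift(arr)),
                    lesion = array(as.integer(shift(lesion)),
                                   dim(lesion)))
  idx1 <- matrix(c(5L, 5L, 5L), 1)
  idx2 <- matrix(c(6L, 5L, 5L), 1)
  v1 <- voxel_features(s1, NULL, idx1, volumes = "t1")
  v2 <- voxel_features(s2, NULL, idx2, volumes = "t1")
  expect_equal(v1$X, v2$X)
  expect_equal(v1$y, v2$y)
})

test_that("background sampling honours the ratio and the seed", {
  coh <- small_cohort()
  s <- coh$subjects$pos01
  n_les <- sum(s$lesion_mask)
  sm <- sample_training_voxels(list(s), ratio = 10, seed = 3)
  expect_equal(nrow(sm[[1]]), n_les + 10 * n_les)
  sm2 <- sample_training_voxels(list(s), ratio = 10, seed = 3)
  expect_identical(sm, sm2)
  ctl <- coh$subjects$ctl01
  smc <- sample_training_voxels(list(ctl), control_quota = 123, seed = 3)
  expect_equal(nrow(smc[[1]]), 123)
  expect_error(sample_training_voxels(list(s), ratio = 0.5), "ratio")
})

test_that("sampling clamps with a warning when background runs out", {
  labels <- array(0L, c(6, 6, 6)); labels[2:5, 2:5, 2:5] <- 1L
  lesion <- array(0L, c(6, 6, 6)); lesion[2:5, 2:5, 2:4] <- 1L
  s <- toy_subject(parcellation_map(labels), list(t1 = 1),
                   lesion = lesion)
  expect_warning(sm <- sample_training_voxels(list(s), ratio = 10,
                                              seed = 1),
                 "background")
  expect_equal(nrow(sm[[1]]), 64)  # 48 lesion + all 16 background
})

test_that("the voxelwise classifier separates a shifted class", {
  set.seed(12)
  n <- 2000
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, c(paste0("v", 1:9), "region_label")))
  X[, "region_label"] <- sample(1:5, n, TRUE)
  y <- rep(0:1, each = n / 2)
  X[y == 1, 2] <- X[y == 1, 2] + 5
  X[y == 1, 7] <- X[y == 1, 7] + 5
  half <- sample(n, n / 2)
  m <- train_c2(X[half, ], y[half], c2_params(nrounds = 50), seed = 6)
  p <- predict_c2(m, X[-half, ])
  yy <- y[-half]
  auc <- mean(outer(p[yy == 1], p[yy == 0], `>`) +
                0.5 * outer(p[yy == 1], p[yy == 0], `==`))
  expect_gt(auc, 0.95)
  expect_true(all(p >= 0 & p <= 1))
  m2 <- train_c2(X[half, ], y[half], c2_params(nrounds = 50), seed = 6)
  expect_identical(predict_c2(m2, X[-half, ]), p)
  expect_error(train_c2(X[y == 0, ], y[y == 0]), "single class")
})

test_that("abnormality maps are proper probability volumes", {
  coh <- small_cohort()
  b <- small_bundle()
  s <- coh$subjects$pos01
  m <- predict_detector(b, s)
  brain <- brain_mask(s$parcellation)
  p <- m$probabilities$data
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[!brain] == 0))
  expect_identical(m$binary, p >= m$threshold)
  # threshold 1 empties the mask when max p < 1
  hi <- abnormality_map(m$probabilities, threshold = 1)
  if (max(p) < 1) expect_equal(sum(hi$binary), 0)
  # trained on separable phantoms, prediction beats the empty mask
  expect_gt(dice_coefficient(m$binary, s$lesion_mask),
            dice_coefficient(array(FALSE, dim(p)), s$lesion_mask))
})
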