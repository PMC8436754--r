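# build an abnormality map with given TRUE voxels on an empty lattice
map_with <- function(voxels, shape = c(30, 30, 30), spacing = c(1, 1, 1)) {
  p <- array(0, dim = shape)
  if (length(voxels)) p[voxels] <- 1
  abnormality_map(volume_grid(p, spacing = spacing), threshold = 0.5)
}

contact_row <- function(id, xyz, onset = 0, propagation = 0,
                        interictal = 0) {
  data.frame(contact_id = id, x_mm = xyz[1], y_mm = xyz[2],
             z_mm = xyz[3], onset = onset, propagation = propagation,
             interictal = interictal)
}

test_that("sphere overlap uses voxel-centre distance in world mm", {
  m <- map_with(matrix(c(15L, 15L, 15L), 1))  # voxel centre at (14,14,14)
  at <- contact_sphere_overlap(c(14, 14, 14), m)
  expect_true(at$overlaps)
  expect_equal(at$min_distance_mm, 0)
  far <- contact_sphere_overlap(c(14, 14, 20), m, diameter_mm = 10)
  expect_false(far$overlaps)          # 6 mm > radius 5
  expect_equal(far$min_distance_mm, 6)
  near <- contact_sphere_overlap(c(14, 14, 18.9), m, diameter_mm = 10)
  expect_true(near$overlaps)          # 4.9 mm < radius 5
  expect_equal(near$min_distance_mm, 4.9)
  # empty mask: infinite distance, no overlap
  empty <- map_with(integer(0))
  e <- contact_sphere_overlap(c(14, 14, 14), empty)
  expect_false(e$overlaps)
  expect_true(is.infinite(e$min_distance_mm))
  expect_warning(contact_sphere_overlap(c(200, 0, 0), m),
                 "bounding box")
})

test_that("overlap is monotone in the sphere diameter", {
  set.seed(61)
  vox <- matrix(sample(5:25, 30, TRUE), ncol = 3)
  m <- map_with(vox)
  contact <- c(3, 3, 3)
  prev <- FALSE
  for (d in seq(1, 40, by = 1)) {
    cur <- contact_sphere_overlap(contact, m, diameter_mm = d)$overlaps
    expect_true(cur >= prev)
    prev <- cur
  }
})

test_that("concordance determinations and group assignment", {
  lesion_vox <- as.matrix(expand.grid(10:12, 10:12, 10:12))
  m <- map_with(lesion_vox)
  centre <- c(10, 10, 10)  # world mm of voxel (11,11,11)
  faraway <- c(27, 27, 27)
  rep_a <- assess_concordance(rbind(
    contact_row("s1", centre, onset = 1),
    contact_row("p1", centre + c(3, 0, 0), propagation = 1)), m)
  expect_true(rep_a$soz_within_abnormal)
  expect_true(rep_a$propagation_within_abnormal)
  expect_false(rep_a$ied_within_abnormal)
  expect_equal(rep_a$group, "A")

  rep_b <- assess_concordance(rbind(
    contact_row("s1", faraway, onset = 1),
    contact_row("i1", centre, interictal = 1)), m)
  expect_false(rep_b$soz_within_abnormal)
  expect_true(rep_b$ied_within_abnormal)
  expect_equal(rep_b$group, "B")

  rep_c <- assess_concordance(rbind(
    contact_row("i1", centre, interictal = 1)), m)
  expect_equal(rep_c$group, "C")

  # empty map: all five determinations false
  empty <- map_with(integer(0))
  rep_e <- assess_concordance(contact_row("s1", centre, onset = 1),
                              empty)
  expect_false(any(unlist(rep_e[c("soz_within_abnormal",
                                  "propagation_within_abnormal",
                                  "ied_within_abnormal",
                                  "abnormal_unsampled",
                                  "abnormal_sampled_silent")])))
  expect_equal(rep_e$group, "B")
  rep_e2 <- assess_concordance(contact_row("x", centre), empty)
  expect_equal(rep_e2$group, "C")
  expect_error(assess_concordance(contact_row("x", centre)[0, ], m),
               "empty")
})

test_that("abnormal areas partition into role / silent / unsampled", {
  # two components: one touched by a silent contact, one untouched
  comp1 <- as.matrix(expand.grid(5:6, 5:6, 5:6))
  comp2 <- as.matrix(expand.grid(22:23, 22:23, 22:23))
  m <- map_with(rbind(comp1, comp2))
  rep <- assess_concordance(contact_row("silent", c(4, 4, 4)), m)
  expect_true(rep$abnormal_sampled_silent)
  expect_true(rep$abnormal_unsampled)
  expect_setequal(rep$component_status, c("sampled_silent", "unsampled"))
  # every component gets exactly one status
  expect_length(rep$component_status,
                attr(label_components(m$binary), "n_components"))

  # adding an onset contact on component 2 flips it to role_overlapped
  rep2 <- assess_concordance(rbind(
    contact_row("silent", c(4, 4, 4)),
    contact_row("s", c(21, 21, 21), onset = 1)), m)
  expect_setequal(rep2$component_status,
                  c("sampled_silent", "role_overlapped"))
  expect_false(rep2$abnormal_unsampled)
  expect_equal(rep2$group, "A")
})

test_that("concordance is invariant to contact ordering", {
  lesion_vox <- as.matrix(expand.grid(10:12, 10:12, 10:12))
  m <- map_with(lesion_vox)
  contacts <- rbind(
    contact_row("a", c(9, 9, 9), onset = 1),
    contact_row("b", c(25, 25, 25), interictal = 1),
    contact_row("c", c(3, 3, 3)))
  r1 <- assess_concordance(contacts, m)
  r2 <- assess_concordance(contacts[c(3, 1, 2), ], m)
  for (k in c("soz_within_abnormal", "propagation_within_abnormal",
              "ied_within_abnormal", "abnormal_unsampled",
              "abnormal_sampled_silent", "group"))
    expect_identical(r1[[k]], r2[[k]])
  expect_equal(sort(names(r1$distances_mm)),
               sort(names(r2$distances_mm)))
})

test_that("phantom contact scenarios reach the expected groups with a
          faithful map", {
  coh <- small_cohort()
  s <- coh$subjects$pos01
  truth_map <- abnormality_map(
    volume_grid(array(as.numeric(s$lesion_mask), dim(s$lesion_mask)),
                s$parcellation$spacing, s$parcellation$affine),
    threshold = 0.5)
  rep_a <- assess_concordance(make_contacts(s, "onset_in_lesion"),
                              truth_map)
  expect_equal(rep_a$group, "A")
  expect_true(rep_a$soz_within_abnormal)
  rep_c <- assess_concordance(
    make_contacts(s, "mixed")[c(2, 3, 4), ], truth_map)
  expect_equal(rep_c$group, "C")
})
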