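test_that("balanced cohorts apportion classes exactly and reproduce bitwise", {
  sp <- phantom_spec(n_cases = 12, seed = 51)
  co <- generate_cohort(sp)
  expect_length(co, 12L)
  expect_identical(as.vector(table(vapply(co, function(x) x$label, 0L))),
                   rep(4L, 3))
  expect_identical(generate_cohort(sp), co)
  # different seed changes the voxel data
  sp2 <- phantom_spec(n_cases = 12, seed = 52)
  co2 <- generate_cohort(sp2)
  expect_false(identical(co[[1]]$ap_volume$data, co2[[1]]$ap_volume$data))
})

test_that("null spec has all class knobs equal; invalid specs are rejected", {
  ns <- phantom_spec_null(n_cases = 6)
  for (f in c("margin_irregularity", "capsule_prob", "enhancement_ap",
              "enhancement_pp", "texture_corr_len_mm"))
    expect_length(unique(ns[[f]]), 1L)
  expect_error(phantom_spec(class_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(phantom_spec(grid_shape = c(10, 10, 10),
                            lesion_radius_mm = c(9, 10)), "too small")
})

test_that("zero-perturbation lesions are voxelized spheres with the planted
           enhancement", {
  sp <- phantom_spec(n_cases = 1, margin_irregularity = rep(0, 3),
                     capsule_prob = rep(0, 3),
                     enhancement_ap = rep(40, 3), noise_sd = 5,
                     lesion_radius_mm = c(10, 10),
                     grid_shape = c(36, 36, 36),
                     voxel_spacing_mm = c(1, 1, 1))
  cc <- generate_case(0, sp, seed = 3)
  M <- cc$mask$data
  # axis-swap symmetry of the discrete sphere (up to voxelization the mask
  # is symmetric under permuting axes about its centroid)
  ctr <- colMeans(which(M == 1, arr.ind = TRUE))
  expect_lt(max(abs(ctr - mean(ctr))), 1e-6 + 2)  # near-isotropic centroid
  expect_equal(sum(M), 4 / 3 * pi * 1000, tolerance = 0.05)
  inm <- M != 0
  diffp <- mean(cc$ap_volume$data[inm]) - mean(cc$ap_volume$data[!inm])
  expect_gte(diffp, 37); expect_lte(diffp, 43)    # CLT bound at this n
  # reader jitter 0 -> identical masks
  expect_identical(perturb_mask(cc$mask, 0, 9), cc$mask)
})

test_that("mask perturbation is bounded, nonempty, seeded and Dice-close", {
  sp <- phantom_spec(n_cases = 1, margin_irregularity = rep(0, 3),
                     capsule_prob = rep(0, 3), lesion_radius_mm = c(10, 10),
                     grid_shape = c(36, 36, 36),
                     voxel_spacing_mm = c(1, 1, 1))
  m <- generate_case(1, sp, seed = 4)$mask
  p1 <- perturb_mask(m, 1, seed = 61)
  expect_gte(dice(m, p1), 0.8)                    # <= 1 mm shift on r = 10
  expect_lte(dice(m, p1), 1)
  p2 <- perturb_mask(m, 1, seed = 62)
  expect_lt(dice(p1, p2), 1)                      # different seeds differ
  expect_gte(dice(m, perturb_mask(m, 2, seed = 63)), 0.5)
  expect_gt(mask_count <- sum(p1$data), 0)
})

test_that("cohorts carry reader masks for the first n_reader_cases and write
           a readable NIfTI manifest", {
  sp <- phantom_spec(n_cases = 4, n_reader_cases = 2, seed = 53)
  co <- generate_cohort(sp)
  expect_false(is.null(co[[1]]$reader2_mask))
  expect_false(is.null(co[[2]]$reader1_repeat_mask))
  expect_null(co[[3]]$reader2_mask)
  d <- tempfile()
  man <- write_cohort(co, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- ingest_manifest(file.path(d, "manifest.csv"))
  expect_length(back, 4L)
  expect_equal(back[[2]]$mask$data, co[[2]]$mask$data)
  expect_equal(back[[1]]$ap_volume$data, co[[1]]$ap_volume$data,
               tolerance = 1e-4)
  unlink(d, recursive = TRUE)
})
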