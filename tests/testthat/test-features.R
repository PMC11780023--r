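test_that("default configuration emits 1781 uniquely named features", {
  set.seed(41)
  v <- volume(array(rnorm(24^3, 120, 30), c(24, 24, 24)))
  m <- mk_sphere_mask(7, pad = 5)
  pp <- preprocess_volume(v, m)
  fv <- extract_features(pp$vol, pp$mask)
  expect_length(fv, 1781L)
  expect_identical(anyDuplicated(names(fv)), 0L)
  expect_true(all(is.finite(fv)))
  # family counts on the original image: 14 shape + 93 others
  orig <- grep("^original_", names(fv), value = TRUE)
  fam <- table(sub("^original_([a-z]+)_.*$", "\\1", orig))
  expect_identical(as.vector(fam[c("shape", "firstorder", "glcm", "glrlm",
                                   "glszm", "gldm", "ngtdm")]),
                   c(14L, 18L, 24L, 16L, 16L, 14L, 5L))
  # names are stable across cases
  v2 <- volume(array(rnorm(24^3, 80, 10), c(24, 24, 24)))
  pp2 <- preprocess_volume(v2, m)
  fv2 <- extract_features(pp2$vol, pp2$mask)
  expect_identical(names(fv2), names(fv))
})

test_that("uniform VOI collapses first-order variance and entropy to zero", {
  v <- volume(array(100, c(8, 8, 8)))
  m <- volume(array(1, c(8, 8, 8)))
  cfg <- radiomics_config(filters = list())
  fv <- extract_features(v, m, cfg)
  expect_equal(fv[["original_firstorder_Variance"]], 0)
  expect_equal(fv[["original_firstorder_Entropy"]], 0)
  expect_equal(fv[["original_glcm_JointEnergy"]], 1)
  expect_equal(fv[["original_glcm_Contrast"]], 0)
})

test_that("first-order mean and variance match closed-form moments", {
  vals <- c(2, 4, 4, 4, 5, 5, 7, 9)
  v <- volume(array(vals, c(8, 1, 1)))
  m <- volume(array(1, c(8, 1, 1)))
  fv <- extract_features(v, m, radiomics_config(filters = list()))
  expect_equal(fv[["original_firstorder_Mean"]], 5)
  expect_equal(fv[["original_firstorder_Variance"]], 4)  # population variance
  expect_equal(fv[["original_firstorder_RootMeanSquared"]],
               sqrt(mean(vals^2)))
  expect_equal(fv[["original_firstorder_Energy"]], sum(vals^2))
})

test_that("mesh surface area is within 2% of the analytic sphere", {
  for (r in c(8, 10)) {
    sf <- dlradiomics:::shape_features(mk_sphere_mask(r))
    expect_lt(abs(sf[["SurfaceArea"]] / (4 * pi * r^2) - 1), 0.02)
    expect_lt(abs(sf[["MeshVolume"]] / (4 / 3 * pi * r^3) - 1), 0.03)
    expect_equal(sf[["Maximum3DDiameter"]], 2 * r, tolerance = 0.05)
    expect_gt(sf[["Sphericity"]], 0.93)
    expect_lte(sf[["Elongation"]], 1)
    expect_equal(sf[["VoxelVolume"]], sum(mk_sphere_mask(r)$data))
  }
})

test_that("intensity/texture features are invariant to translating the VOI", {
  set.seed(42)
  d <- c(14, 14, 14)
  tex <- array(rnorm(14^3, 100, 20), d)
  v1 <- volume(array(0, d)); v1$data[2:7, 2:7, 2:7] <- tex[2:7, 2:7, 2:7]
  v2 <- volume(array(0, d)); v2$data[8:13, 8:13, 8:13] <- tex[2:7, 2:7, 2:7]
  m1 <- volume(array(0, d)); m1$data[2:7, 2:7, 2:7] <- 1
  m2 <- volume(array(0, d)); m2$data[8:13, 8:13, 8:13] <- 1
  cfg <- radiomics_config(filters = list())
  f1 <- extract_features(v1, m1, cfg)
  f2 <- extract_features(v2, m2, cfg)
  keep <- grep("firstorder|glcm|glrlm|glszm|gldm|ngtdm", names(f1))
  expect_equal(f1[keep], f2[keep], tolerance = 1e-10)
})

test_that("empty or mismatched masks raise case-level errors", {
  v <- volume(array(1, c(4, 4, 4)))
  expect_error(extract_features(v, volume(array(0, c(4, 4, 4)))), "empty")
  expect_error(extract_features(v, volume(array(1, c(5, 4, 4)))), "shape")
})
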