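# Hand-derived worked examples for the five texture matrix families, plus a
# quick oracle spot-check (the full 200-instance oracle equivalence runs in
# test-acceptance.R).

test_that("GLCM matches the worked 2x2 example and normalizes to 1", {
  v <- as_dvoi(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE))
  g <- compute_glcm(v, directions = matrix(c(0, 1, 0), 1))
  expect_equal(g$values, matrix(c(0.5, 0.25, 0.25, 0), 2, 2), tolerance = 1e-12)
  u <- compute_glcm(as_dvoi(array(1L, c(2, 2, 2))))
  expect_equal(u$values, matrix(1, 1, 1))
  set.seed(31)
  for (i in 1:20) {
    tm <- compute_glcm(random_dvoi())
    for (m in tm$meta$matrices) expect_equal(sum(m), 1, tolerance = 1e-12)
  }
})

test_that("GLRLM matches run enumeration and the voxel-count identity", {
  r <- compute_glrlm(as_dvoi(array(c(1, 1, 2), c(1, 3, 1))),
                     directions = matrix(c(0, 1, 0), 1))
  expect_equal(r$values, matrix(c(0, 1, 1, 0), 2, 2))
  # uniform 1xn line is a single run
  rn <- compute_glrlm(as_dvoi(array(1L, c(1, 5, 1))),
                      directions = matrix(c(0, 1, 0), 1))
  expect_equal(rn$values[1, ], c(0, 0, 0, 0, 1))
  set.seed(32)
  for (i in 1:20) {
    dv <- random_dvoi()
    n_vox <- sum(dv$levels > 0)
    for (m in compute_glrlm(dv)$meta$matrices) {
      j <- seq_len(ncol(m))
      expect_equal(sum(t(m) * j), n_vox)
    }
  }
})

test_that("GLSZM matches zone labelling, including the 26-adjacent diagonal", {
  s <- compute_glszm(as_dvoi(matrix(c(1, 1, 2, 1), 2, 2, byrow = TRUE)))
  expect_equal(s$values[1, 3], 1)
  expect_equal(s$values[2, 1], 1)
  # checkerboard: diagonals are 26-adjacent, so two zones of size 2
  s2 <- compute_glszm(as_dvoi(matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)))
  expect_equal(s2$values, matrix(c(0, 0, 1, 1), 2, 2))
})

test_that("GLDM matches the neighbour-count convention (d from 0)", {
  dm <- compute_gldm(as_dvoi(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)),
                     alpha = 0)
  expect_equal(dm$values[1, 3], 3)   # three level-1 voxels with d = 2
  expect_equal(dm$values[2, 1], 1)   # the level-2 voxel with d = 0
  set.seed(33)
  for (i in 1:20) {
    dv <- random_dvoi()
    expect_equal(sum(compute_gldm(dv)$values), sum(dv$levels > 0))
  }
})

test_that("NGTDM matches the worked neighbour means and p sums to 1", {
  nt <- compute_ngtdm(as_dvoi(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)))
  expect_equal(unname(nt$values[, "n"]), c(3, 1))
  expect_equal(unname(nt$values[, "s"]), c(1, 1), tolerance = 1e-12)
  set.seed(34)
  for (i in 1:20) {
    nv <- compute_ngtdm(random_dvoi())$values
    expect_equal(sum(nv[, "p"]), 1, tolerance = 1e-12)
    # uniform VOI: all s are 0
  }
  un <- compute_ngtdm(as_dvoi(array(1L, c(3, 3, 1))))
  expect_true(all(un$values[, "s"] == 0))
})

test_that("builders agree with brute-force enumeration on random VOIs", {
  set.seed(35)
  for (i in 1:25) {
    dv <- random_dvoi()
    L <- dv$levels
    off <- all_offsets26[sample(13, 1), ]
    bg <- glcm_brute(L, off)
    if (!is.null(bg)) {
      tg <- compute_glcm(dv, directions = matrix(off, 1))
      expect_equal(tg$values, bg, tolerance = 1e-12)
    }
    br <- glrlm_brute(L, off)
    if (!is.null(br)) {
      tr_ <- compute_glrlm(dv, directions = matrix(off, 1))
      nc <- max(ncol(br), ncol(tr_$values))
      expect_equal(pad_cols(tr_$values, nc), pad_cols(br, nc))
    }
    expect_equal(compute_glszm(dv)$values, glszm_brute(L))
    expect_equal(compute_gldm(dv, 0)$values, gldm_brute(L, 0))
    expect_equal(compute_ngtdm(dv)$values, ngtdm_brute(L),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("texture matrices are invariant to mask translation", {
  set.seed(36)
  L <- array(0L, c(6, 6, 6))
  L[2:4, 2:4, 2:4] <- sample.int(3, 27, replace = TRUE)
  L2 <- array(0L, c(6, 6, 6))
  L2[3:5, 3:5, 3:5] <- L[2:4, 2:4, 2:4]
  a <- as_dvoi(L); b <- as_dvoi(L2)
  expect_equal(compute_glcm(a)$values, compute_glcm(b)$values)
  expect_equal(compute_glszm(a)$values, compute_glszm(b)$values)
  expect_equal(compute_gldm(a)$values, compute_gldm(b)$values)
  expect_equal(compute_ngtdm(a)$values, compute_ngtdm(b)$values)
})
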