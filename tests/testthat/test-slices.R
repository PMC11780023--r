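mk_mask_from_areas <- function(areas) {
  # build a mask whose per-slice tumor areas follow `areas`
  d <- c(8, 8, length(areas))
  m <- array(0, d)
  for (z in seq_along(areas)) {
    if (areas[z] > 0) m[seq_len(areas[z]), 1, z] <- 1
  }
  volume(m)
}

test_that("Max-ROI selection is the argmax with lowest-index tie-breaking", {
  expect_identical(select_max_roi(mk_mask_from_areas(c(0, 3, 7, 5, 5, 2, 0))), 3L)
  expect_identical(select_max_roi(mk_mask_from_areas(c(4, 7, 7, 1))), 2L)
  sph <- mk_sphere_mask(5)
  areas <- apply(sph$data, 3, sum)
  expect_identical(select_max_roi(sph), which.max(areas))
  expect_identical(areas[select_max_roi(sph)], max(areas))
  expect_error(select_max_roi(volume(array(0, c(3, 3, 3)))), "empty")
})

test_that("stacks hold 5 crops equal to the per-slice bounding rectangles", {
  set.seed(71)
  m <- volume(array(0, c(12, 12, 9)))
  m$data[3:5, 2:7, 3:7] <- 1       # rows 3..5, cols 2..7 on slices 3..7
  v <- volume(array(runif(12 * 12 * 9, 0, 255), c(12, 12, 9)))
  st <- extract_stack(v, m, "c1", "AP")
  expect_s3_class(st, "slice_stack")
  expect_length(st$images, 5L)
  expect_identical(st$offsets, -2:2)
  for (img in st$images) expect_identical(dim(img), c(3L, 6L))
  expect_identical(unname(st$crop_boxes[3, ]), c(2L, 5L, 1L, 7L))  # 0-based
  # crop content equals the sub-matrix of the source
  expect_identical(st$images[[3]], v$data[3:5, 2:7, st$slice_index[3]])
  # determinism
  expect_identical(extract_stack(v, m, "c1", "AP"), st)
})

test_that("offset slices without tumor fall back to the nearest tumor-bearing
           slice with a warning", {
  m <- volume(array(0, c(10, 10, 9)))
  m$data[4:6, 4:6, 4] <- 1
  m$data[4:7, 4:7, 5] <- 1         # Max-ROI at slice 5
  m$data[4:6, 4:6, 6] <- 1
  v <- volume(array(1, c(10, 10, 9)))
  expect_warning(st <- extract_stack(v, m), "no tumor")
  expect_identical(st$slice_index, c(4L, 4L, 5L, 6L, 6L))
  for (i in 1:5)
    expect_gt(sum(m$data[, , st$slice_index[i]]), 0)
})

test_that("a cohort yields 5 x phases x cases PNG exports", {
  sp <- phantom_spec(n_cases = 3, seed = 72)
  co <- generate_cohort(sp)
  st <- cohort_stacks(co)
  expect_length(st, 6L)            # 3 cases x 2 phases
  d <- tempfile()
  man <- export_stacks(st, d)
  pngs <- list.files(d, pattern = "\\.png$")
  expect_length(pngs, 30L)         # 5 x 2 x 3
  expect_identical(nrow(man), 30L)
  img <- png::readPNG(file.path(d, pngs[1]))
  expect_true(all(img >= 0 & img <= 1))
  unlink(d, recursive = TRUE)
})
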