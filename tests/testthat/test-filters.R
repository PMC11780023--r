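test_that("filter bank emits the 18 default derived images with stable labels", {
  set.seed(21)
  v <- normalize_0_255(volume(array(rnorm(12^3), c(12, 12, 12))))
  bank <- filter_bank(v)
  expect_identical(names(bank)[1], "original")
  expect_length(bank, 19L)
  expect_length(grep("^wavelet-", names(bank)), 8L)
  expect_identical(grep("^log-sigma", names(bank), value = TRUE),
                   sprintf("log-sigma-%.1f", c(2, 3, 4, 5)))
  expect_true(all(c("square", "squareroot", "logarithm", "exponential",
                    "gradient", "lbp2d") %in% names(bank)))
  for (b in bank) expect_identical(dim(b$data), dim(v$data))
})

test_that("LoG of a constant volume is ~0; intensity transforms hit their
           closed forms on constants", {
  cst <- volume(array(100, c(16, 16, 16)))
  lg <- apply_filter(cst, list(kind = "log", sigmas_mm = c(2, 4)))
  expect_length(lg, 2L)
  for (l in lg) expect_lt(max(abs(l$data)), 1e-6 * 255)
  sq <- apply_filter(cst, list(kind = "square"))[[1]]
  expect_equal(unique(as.vector(sq$data)), 100^2 / 255)
  sr <- apply_filter(cst, list(kind = "squareroot"))[[1]]
  expect_equal(unique(as.vector(sr$data)), sqrt(255 * 100))
  ex <- apply_filter(cst, list(kind = "exponential"))[[1]]
  expect_equal(unique(as.vector(ex$data)), expm1(100 / 255 * log(256)))
})

test_that("wavelet decomposition yields exactly 8 labelled sub-bands and the
           LLL band of a constant is the constant", {
  cst <- volume(array(10, c(8, 8, 8)))
  wb <- apply_filter(cst, list(kind = "wavelet"))
  expect_identical(sort(names(wb)),
                   sort(paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                             "HLL", "HLH", "HHL", "HHH"))))
  # Haar low-pass gain is sqrt(2) per axis; high-pass of a constant is 0
  expect_equal(unique(round(as.vector(wb[["wavelet-LLL"]]$data), 9)),
               round(10 * 2^(3 / 2), 9))
  expect_lt(max(abs(wb[["wavelet-HHH"]]$data)), 1e-9)
})

test_that("gradient magnitude matches the analytic slope of a ramp", {
  d <- c(10, 10, 10)
  ramp <- volume(array(rep(seq_len(10) * 3, times = 100), d),
                 spacing_mm = c(1.5, 1, 1))
  g <- apply_filter(ramp, list(kind = "gradient"))[[1]]
  interior <- g$data[3:8, 3:8, 3:8]
  expect_equal(unique(round(as.vector(interior), 9)), 3 / 1.5)
})

test_that("LBP codes are integers in 0..255 and constant images give a
           constant code", {
  set.seed(22)
  v <- volume(array(runif(8^3, 0, 255), c(8, 8, 8)))
  lb <- apply_filter(v, list(kind = "lbp2d"))[[1]]
  expect_true(all(lb$data == round(lb$data)))
  expect_gte(min(lb$data), 0)
  expect_lte(max(lb$data), 255)
  cst <- apply_filter(volume(array(5, c(6, 6, 2))), list(kind = "lbp2d"))[[1]]
  expect_length(unique(as.vector(cst$data)), 1L)  # ties all resolve the same
})
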