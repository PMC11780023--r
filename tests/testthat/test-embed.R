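test_that("backend dimension contracts are enforced", {
  expect_identical(backend_spec("vit")$embed_dim, 1024L)
  expect_identical(backend_spec("vgg19")$embed_dim, 4096L)
  expect_identical(backend_spec("googlenet")$embed_dim, 1024L)
  expect_identical(backend_spec("inception_v3")$embed_dim, 2048L)
  expect_identical(backend_spec("inception_v3")$input_size, c(299L, 299L))
  expect_error(backend_spec("vgg19", embed_dim = 512), "fixed at 4096")
  expect_identical(backend_spec("pseudo", embed_dim = 64)$embed_dim, 64L)
})

test_that("embeddings are deterministic, content-sensitive, and honor dims", {
  set.seed(81)
  img <- matrix(runif(30 * 25, 0, 255), 30, 25)
  b <- backend_spec("pseudo", embed_dim = 64, seed = 7)
  v1 <- embed_slice(img, b)
  expect_length(v1, 64L)
  expect_true(all(is.finite(v1)))
  expect_identical(embed_slice(img, b), v1)
  img2 <- img; img2[1:10, 1:10] <- 255 - img2[1:10, 1:10]
  expect_false(identical(embed_slice(img2, b), v1))
  # seeds change the filterbank
  v_other <- embed_slice(img, backend_spec("pseudo", embed_dim = 64, seed = 8))
  expect_false(identical(v_other, v1))
  # named backend with random weights produces its contracted length
  expect_length(embed_slice(img, backend_spec("vgg19")), 4096L)
})

test_that("pretrained weights are refused with a pseudo-fallback message", {
  img <- matrix(1:20, 4, 5)
  expect_error(embed_slice(img, backend_spec("vgg19", weights = "pretrained")),
               "pseudo")
})

test_that("slice aggregation is the permutation-invariant mean", {
  vs <- list(c(1, 0), c(0, 1), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(aggregate_case(vs), c(0.2, 0.2))
  v <- c(3, -1, 2)
  expect_equal(aggregate_case(rep(list(v), 5)), v)
  set.seed(82)
  vs2 <- lapply(1:5, function(i) rnorm(6))
  perm <- vs2[c(3, 5, 1, 4, 2)]
  expect_equal(aggregate_case(vs2), aggregate_case(perm))
  expect_equal(aggregate_case(vs2, "max"), aggregate_case(perm, "max"))
  expect_error(aggregate_case(vs2[1:4]), "exactly 5")
  expect_error(aggregate_case(c(vs2[1:4], list(rnorm(3)))), "length")
})

test_that("cohort embedding tables are complete and reproducible", {
  sp <- phantom_spec(n_cases = 2, seed = 83)
  co <- generate_cohort(sp)
  st <- cohort_stacks(co)
  b <- backend_spec("pseudo", embed_dim = 16, seed = 9)
  tab <- deep_feature_table(st, b)
  expect_identical(dim(tab), c(2L, 32L))          # 2 phases x 16
  expect_false(anyNA(tab))
  expect_identical(deep_feature_table(st, b), tab)
  expect_length(grep("^AP_pseudo_dtl_", colnames(tab)), 16L)
})
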