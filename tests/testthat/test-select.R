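test_that("ICC(2,1) is 1 on perfect agreement and ~0 for independent noise", {
  set.seed(91)
  f1 <- as.data.frame(matrix(rnorm(30 * 40), 30))
  colnames(f1) <- paste0("x", 1:40)
  ic <- icc_filter(f1, f1, f1)
  expect_true(all(ic$inter_icc > 0.999))
  expect_true(all(ic$retained))
  # independent second reader: mean inter-ICC within +-0.15 of 0
  f2 <- as.data.frame(matrix(rnorm(30 * 40), 30)); colnames(f2) <- colnames(f1)
  ic2 <- icc_filter(f1, f2, f1)
  expect_lt(abs(mean(ic2$inter_icc)), 0.15)
  expect_identical(sum(ic2$retained), 0L)
  # both-above-threshold rule
  n <- 30
  base <- rnorm(n)
  good <- base + rnorm(n, 0, 0.05)       # high ICC with base
  bad <- base + rnorm(n, 0, 2)           # low ICC with base
  df1 <- data.frame(a = base); df2 <- data.frame(a = good)
  df3 <- data.frame(a = bad)
  ic3 <- icc_filter(df1, df2, df3)       # inter high, intra low
  expect_false(ic3$retained[1])
  # zero-variance feature drops with a warning
  z1 <- data.frame(a = rep(1, 30)); z2 <- z1; z3 <- z1
  expect_warning(icz <- icc_filter(z1, z2, z3), "zero variance")
  expect_false(icz$retained[1])
  expect_error(icc_filter(f1[1:5, ], f1[1:5, ], f1[1:5, ]), "at least 10")
})

test_that("z-scoring uses training statistics only (sample sd)", {
  tr <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  z <- zscore(tr, newdata = matrix(4, 1, 1, dimnames = list(NULL, "a")))
  expect_equal(as.vector(z$train), c(-1, 0, 1))
  expect_equal(as.vector(z$newdata), 2)
  expect_equal(unname(z$center), 2)
  expect_equal(unname(z$scale), 1)
  set.seed(92)
  X <- matrix(rnorm(50 * 4, 5, 3), 50)
  colnames(X) <- letters[1:4]
  z2 <- zscore(X[1:30, ], X[31:50, ])
  expect_equal(unname(colMeans(z2$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z2$train, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # test rows need not be centred
  expect_gt(max(abs(colMeans(z2$newdata))), 1e-6)
  # zero-variance columns dropped with warning
  X[, 2] <- 7
  expect_warning(z3 <- zscore(X), "zero-variance")
  expect_identical(colnames(z3$train), c("a", "c", "d"))
})

test_that("LASSO selects nothing at lambda_max and recovers planted signal", {
  set.seed(93)
  n <- 200
  y <- rep(0:2, length.out = n)
  X <- matrix(rnorm(n * 53), n)
  colnames(X) <- paste0("f", 1:53)
  for (k in 1:3) X[, k] <- X[, k] + 2 * (y == (k - 1))
  Xz <- zscore(X)$train
  sr <- lasso_select(Xz, y, seed = 7)
  expect_s3_class(sr, "selection_result")
  expect_gte(sr$lambda_1se, sr$lambda_min)
  expect_identical(length(sr$select_at(sr$lambda_max)), 0L)
  expect_true(all(c("f1", "f2", "f3") %in% sr$selected_names))
  # determinism under the seed
  sr2 <- lasso_select(Xz, y, seed = 7)
  expect_identical(sr2$lambda_1se, sr$lambda_1se)
  expect_identical(sr2$selected_names, sr$selected_names)
  # stratification error when a class has fewer cases than folds
  ybad <- c(rep(0, 3), rep(1, 100), rep(2, 97))
  expect_error(lasso_select(Xz, ybad, seed = 1), "stratification")
})

test_that("fusion pruning drops duplicates, follows the greedy chain rule,
           and keeps independent features", {
  set.seed(94)
  n <- 500
  A <- rnorm(n)
  B <- A + rnorm(n, 0, 0.1)           # rho(A, B) > 0.9
  C <- rnorm(n)                        # independent
  tab <- data.frame(rad_A = A, rad_B = B, dtl_C = C)
  fs <- fuse_and_prune(c("rad_A", "rad_B"), "dtl_C", tab)
  expect_identical(fs$members, c("rad_A", "dtl_C"))
  expect_identical(fs$dropped_pairs$dropped, "rad_B")
  # exact duplicate
  tab2 <- data.frame(rad_A = A, dtl_B = A)
  fs2 <- fuse_and_prune("rad_A", "dtl_B", tab2)
  expect_identical(fs2$members, "rad_A")
  expect_equal(abs(fs2$dropped_pairs$spearman_rho), 1)
  # chain: rho(A,B) and rho(B,C) above the ceiling, rho(A,C) below it.
  # The greedy scan keeps A, drops B against A, then keeps C because it is
  # only compared against the kept A.  (Note a chain with both high rhos
  # and a *low* rho(A,C) is not a valid correlation matrix; 0.85 is.)
  R <- matrix(c(1, 0.97, 0.86, 0.97, 1, 0.945, 0.86, 0.945, 1), 3, 3)
  Z <- matrix(rnorm(3000 * 3), 3000) %*% chol(R)
  tab3 <- data.frame(f_A = Z[, 1], f_B = Z[, 2], g_C = Z[, 3])
  rho <- cor(tab3, method = "spearman")
  expect_gt(abs(rho["f_A", "f_B"]), 0.9)
  expect_gt(abs(rho["f_B", "g_C"]), 0.9)
  expect_lte(abs(rho["f_A", "g_C"]), 0.9)
  fs3 <- fuse_and_prune(c("f_A", "f_B"), "g_C", tab3)
  expect_identical(fs3$members, c("f_A", "g_C"))
  # independent columns: nothing dropped, invariant holds
  Xi <- as.data.frame(matrix(rnorm(n * 8), n))
  colnames(Xi) <- paste0("v", 1:8)
  fs4 <- fuse_and_prune(paste0("v", 1:4), paste0("v", 5:8), Xi)
  expect_length(fs4$members, 8L)
  rho4 <- cor(as.matrix(Xi[, fs4$members]), method = "spearman")
  expect_lte(max(abs(rho4[upper.tri(rho4)])), 0.9)
  # overlapping name spaces are rejected
  expect_error(fuse_and_prune("v1", "v1", Xi), "overlap")
})

test_that("selection reports and feature tables persist with provenance", {
  set.seed(95)
  X <- matrix(rnorm(60 * 10), 60)
  colnames(X) <- paste0("f", 1:10)
  y <- rep(0:2, each = 20)
  sr <- lasso_select(zscore(X)$train, y, seed = 1)
  f <- tempfile(fileext = ".json")
  write_selection_report(sr, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$lambda_1se, sr$lambda_1se)
  expect_identical(length(back$lambda_grid), length(sr$lambda_grid))
  tab <- as.data.frame(X)
  rownames(tab) <- sprintf("case_%02d", 1:60)
  fcsv <- tempfile(fileext = ".csv")
  write_feature_table(tab, fcsv, radiomics_config(filters = list()))
  rt <- utils::read.csv(fcsv)
  expect_identical(rt$case_id[1], "case_01")
  expect_true(file.exists(paste0(fcsv, ".json")))
  unlink(c(f, fcsv, paste0(fcsv, ".json")))
})
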