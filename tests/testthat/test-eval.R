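test_that("stratified split reproduces the 306 -> 244/62 apportionment", {
  lab <- rep(0:2, c(108, 102, 96))
  s <- stratified_split(lab, seed = 1)
  expect_identical(sum(s == "train"), 244L)
  expect_identical(sum(s == "internal_test"), 62L)
  # per-class largest-remainder quotas: 22/21/19
  expect_identical(as.vector(table(lab[s == "internal_test"])), c(22L, 21L, 19L))
  # n = 10, two balanced classes -> one test case each
  s10 <- stratified_split(rep(0:1, each = 5), seed = 2)
  expect_identical(sum(s10 == "internal_test"), 2L)
  expect_identical(as.vector(table(rep(0:1, each = 5)[s10 == "internal_test"])),
                   c(1L, 1L))
  # determinism and seed sensitivity
  expect_identical(stratified_split(lab, seed = 1), s)
  expect_false(identical(stratified_split(lab, seed = 3), s))
  # external cases never enter train or internal test
  tags <- c(rep("train_pool", 300), rep("external", 6))
  se <- stratified_split(lab, tags, seed = 1)
  expect_true(all(se[301:306] == "external_test"))
  expect_identical(sum(se == "external_test"), 6L)
})

test_that("classifier bank separates 3 Gaussian blobs and rejects unknowns", {
  set.seed(101)
  n <- 60
  y <- rep(0:2, each = n / 3)
  X <- matrix(rnorm(n * 2, sd = 0.3), n)
  X[, 1] <- X[, 1] + c(0, 4, 8)[y + 1]
  colnames(X) <- c("u", "v")
  for (cl in c("svm", "rf")) {
    m <- train_model(list(classifier = cl, seed = 5, rf_trees = 200), X, y)
    P <- predict_proba(m, X)
    expect_identical(dim(P), c(60L, 3L))
    expect_equal(unname(rowSums(P)), rep(1, n), tolerance = 1e-9)
    expect_equal(mean((0:2)[max.col(P)] == y), 1)
    P2 <- predict_proba(train_model(list(classifier = cl, seed = 5,
                                         rf_trees = 200), X, y), X)
    expect_identical(P2, P)                      # same data/seed -> same model
  }
  for (cl in c("lr", "dt")) {
    m <- train_model(list(classifier = cl, seed = 5), X, y)
    expect_equal(mean((0:2)[max.col(predict_proba(m, X))] == y), 1)
  }
  expect_error(train_model(list(classifier = "xgb"), X, y), "unknown")
})

test_that("evaluation metrics are exact on perfect scores and chance-level on
           label-independent scores", {
  y <- rep(0:2, each = 2)
  Pperf <- diag(3)[y + 1, ]
  ev <- evaluate(Pperf, y = y, n_bootstrap = 200, seed = 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_auc, 1)
  expect_equal(ev$f1, 1)
  expect_equal(unname(diag(ev$confusion_matrix)), rep(2L, 3))
  expect_equal(sum(ev$confusion_matrix), 6L)
  set.seed(102)
  yn <- rep(0:2, each = 200)
  Pn <- matrix(runif(600 * 3), 600)
  Pn <- Pn / rowSums(Pn)
  evn <- evaluate(Pn, y = yn, n_bootstrap = 200, seed = 2)
  expect_gte(evn$macro_auc, 0.45)
  expect_lte(evn$macro_auc, 0.55)
  # CI brackets the point estimate
  expect_lte(evn$ci_95[["low"]], evn$macro_auc + 0.02)
  expect_gte(evn$ci_95[["high"]], evn$macro_auc - 0.02)
})

test_that("macro-AUC reduces to the two-class AUC when a class is absent", {
  set.seed(103)
  y <- rep(0:1, each = 40)
  s1 <- rnorm(80) + y                     # score for class 1
  P <- cbind(1 - plogis(s1), plogis(s1), 0)
  expect_warning(ev <- evaluate(P, y = y, n_bootstrap = 100, seed = 3),
                 "absent")
  auc2 <- (function(scores, pos) {
    r <- rank(scores); n1 <- sum(pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!pos))
  })(s1, y == 1)
  expect_equal(ev$macro_auc, auc2, tolerance = 1e-12)
})

test_that("micro and macro AUC agree on balanced well-calibrated toy data", {
  set.seed(104)
  y <- rep(0:2, each = 50)
  P <- matrix(0.1, 150, 3)
  P[cbind(seq_len(150), y + 1)] <- 0.8    # same calibrated score pattern
  ev <- evaluate(P, y = y, n_bootstrap = 100, seed = 4)
  expect_equal(ev$micro_auc, ev$macro_auc, tolerance = 1e-12)
  expect_equal(ev$macro_auc, 1)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(105)
  mk <- function(n) {
    y <- rep(0:2, each = n / 3)
    s <- matrix(rnorm(n * 3), n)
    s[cbind(seq_len(n), y + 1)] <- s[cbind(seq_len(n), y + 1)] + 1.5
    evaluate(exp(s) / rowSums(exp(s)), y = y, n_bootstrap = 400, seed = 6)
  }
  w100 <- diff(unname(mk(99)$ci_95))
  w400 <- diff(unname(mk(399)$ci_95))
  expect_lt(w400, w100)
})

test_that("model comparison ranks by macro-AUC with accuracy tie-breaking", {
  mkrep <- function(auc, acc, f1, name) {
    structure(list(model_name = name, split_id = "s1", macro_auc = auc,
                   micro_auc = auc, accuracy = acc, precision = acc,
                   recall = acc, f1 = f1, ci_95 = c(low = auc, high = auc),
                   n = 10), class = "eval_report")
  }
  tab <- compare_models(list(mkrep(0.9, 0.8, 0.8, "a"),
                             mkrep(0.95, 0.7, 0.7, "b")))
  expect_identical(tab$model[1], "b")
  tab2 <- compare_models(list(mkrep(0.9, 0.80, 0.8, "a"),
                              mkrep(0.9, 0.85, 0.8, "b")))
  expect_identical(tab2$model[1], "b")
  expect_identical(nrow(compare_models(list(mkrep(0.9, 0.8, 0.8, "solo")))), 1L)
  r2 <- mkrep(0.9, 0.8, 0.8, "c"); r2$split_id <- "s2"
  expect_error(compare_models(list(mkrep(0.9, 0.8, 0.8, "a"), r2)),
               "different splits")
})
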