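#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater: the standard
#' form for reader-reproducibility filtering.
#'
#' @param x numeric matrix, rows = cases, columns = raters/sessions.
#' @return ICC estimate (NA when the feature has no variance across cases).
#' @export
icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  rm_ <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sst <- sum((x - gm)^2)
  sse <- sst - k * sum((rm_ - gm)^2) - n * sum((cm - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= 0) return(NA_real_)
  (msr - mse) / den
}

#' Reader-reproducibility (ICC) feature filter
#'
#' Computes inter-reader ICC(2,1) (reader 1 vs reader 2) and intra-reader
#' ICC (reader 1 vs reader-1 repeat) per feature over the reproducibility
#' cases, and retains features with both ICCs at or above the threshold.
#' Zero-variance features have undefined ICC and are dropped with a warning.
#'
#' @param reader1,reader2,reader1_repeat data.frames with identical feature
#'   columns over the same cases (>= 10).
#' @param threshold stability cutoff (default 0.8, the "high stability"
#'   level; 0.5 marks the moderate band).
#' @return data.frame with per-feature `inter_icc`, `intra_icc`, `retained`.
#' @export
icc_filter <- function(reader1, reader2, reader1_repeat, threshold = 0.8) {
  stopifnot(identical(colnames(reader1), colnames(reader2)),
            identical(colnames(reader1), colnames(reader1_repeat)),
            nrow(reader1) == nrow(reader2),
            nrow(reader1) == nrow(reader1_repeat))
  if (nrow(reader1) < 10) stop("need at least 10 reproducibility cases")
  feats <- colnames(reader1)
  inter <- vapply(feats, function(f)
    icc21(cbind(reader1[[f]], reader2[[f]])), 0)
  intra <- vapply(feats, function(f)
    icc21(cbind(reader1[[f]], reader1_repeat[[f]])), 0)
  und <- is.na(inter) | is.na(intra)
  if (any(und))
    warning(sum(und), " feature(s) with undefined ICC (zero variance) dropped")
  retained <- !und & inter >= threshold & intra >= threshold
  data.frame(feature = feats, inter_icc = inter, intra_icc = intra,
             retained = retained, row.names = NULL)
}

#' Z-score standardization fitted on training rows only
#'
#' Column means and sample SDs come from `train`; the same affine transform
#' is applied to `apply` (whose columns therefore need not have mean 0).
#' Zero-variance training columns are dropped from both with a warning.
#'
#' @param train training data.frame/matrix.
#' @param newdata optional rows to transform with the training parameters.
#' @return list with `train`, `newdata`, `center`, `scale`, `dropped`.
#' @export
zscore <- function(train, newdata = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  drop <- !is.finite(scl) | scl <= 0
  if (any(drop))
    warning(sum(drop), " zero-variance feature(s) dropped: ",
            paste(utils::head(colnames(train)[drop], 3), collapse = ", "),
            if (sum(drop) > 3) ", ..." else "")
  keep <- !drop
  tz <- scale(train[, keep, drop = FALSE], ctr[keep], scl[keep])
  az <- if (!is.null(newdata)) {
    a <- as.matrix(newdata)[, colnames(train)[keep], drop = FALSE]
    scale(a, ctr[keep], scl[keep])
  }
  list(train = tz, newdata = az, center = ctr[keep], scale = scl[keep],
       dropped = colnames(train)[drop])
}

#' LASSO feature selection with the one-standard-error rule
#'
#' Fits an L1-penalized multinomial logistic path (glmnet) over a log-spaced
#' lambda grid descending from the first all-zero lambda, estimates per-lambda
#' multinomial deviance by stratified n-fold cross-validation, and selects
#' the sparsest acceptable model: the largest lambda whose mean CV loss is
#' within one standard error of the minimum.  Selected features are those
#' with a nonzero coefficient for any class at `lambda_1se`.
#'
#' @param X standardized numeric matrix (rows = training cases).
#' @param y integer labels in `{0, 1, 2}` (or a factor).
#' @param n_folds folds (default 5); every class needs >= `n_folds` cases.
#' @param seed fold-assignment seed.
#' @return list of class `selection_result`: `lambda_grid`, `cv_loss_mean`,
#'   `cv_loss_se`, `lambda_min`, `lambda_1se`, `lambda_max`,
#'   `selected_names`, and the fitted `cv_fit`.
#' @export
lasso_select <- function(X, y, n_folds = 5L, seed = 0L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  tb <- table(y)
  if (any(tb < n_folds))
    stop("stratification error: every class needs at least ", n_folds,
         " cases (got ", paste(tb, collapse = "/"), ")")
  foldid <- integer(length(y))
  run_seeded(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  cv <- glmnet::cv.glmnet(X, y, family = "multinomial", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  sel_at <- function(lam) {
    cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = lam)
    nz <- Reduce(`|`, lapply(cf, function(m) as.matrix(m)[-1, 1] != 0))
    colnames(X)[nz]
  }
  structure(list(lambda_grid = cv$lambda,
                 cv_loss_mean = cv$cvm,
                 cv_loss_se = cv$cvsd,
                 lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se,
                 lambda_max = cv$lambda[1],
                 selected_names = sel_at(cv$lambda.1se),
                 n_folds = n_folds, seed = seed, cv_fit = cv,
                 select_at = sel_at),
            class = "selection_result")
}

#' Write a selection report as JSON
#'
#' Persists the lambda grid, per-lambda CV loss mean/SE, the chosen
#' `lambda_min` / `lambda_1se` and the selected feature names.
#'
#' @param sel a `selection_result` from [lasso_select].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(
    list(lambda_grid = sel$lambda_grid, cv_loss_mean = sel$cv_loss_mean,
         cv_loss_se = sel$cv_loss_se, lambda_min = sel$lambda_min,
         lambda_1se = sel$lambda_1se, lambda_max = sel$lambda_max,
         selected_names = sel$selected_names, n_folds = sel$n_folds,
         seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> %d lambdas, lambda_min %.4g, ",
                     "lambda_1se %.4g, %d feature(s) selected\n"),
              length(x$lambda_grid), x$lambda_min, x$lambda_1se,
              length(x$selected_names)))
  invisible(x)
}

#' Fuse radiomics and deep selections with Spearman correlation pruning
#'
#' Concatenates the two selected feature sets (radiomics first, then deep;
#' name prefixes keep the spaces disjoint), computes pairwise Spearman rank
#' correlations on the training rows, and greedily scans in that fixed
#' order: a feature is dropped when its absolute correlation with any
#' earlier kept feature exceeds `rho_max`.  The result satisfies
#' `max |rho| <= rho_max` among members on the training data.
#'
#' @param selected_radiomics,selected_deep character vectors of column names.
#' @param train_table data.frame holding the training rows for all of them.
#' @param rho_max correlation ceiling (default 0.9).
#' @return list of class `fusion_set`: `members`, `dropped_pairs`.
#' @export
fuse_and_prune <- function(selected_radiomics, selected_deep, train_table,
                           rho_max = 0.9) {
  members <- c(selected_radiomics, selected_deep)
  if (anyDuplicated(members))
    stop("radiomics and deep feature name spaces overlap")
  if (!length(members))
    return(structure(list(members = character(),
                          dropped_pairs = data.frame()),
                     class = "fusion_set"))
  M <- as.matrix(train_table[, members, drop = FALSE])
  rho <- stats::cor(M, method = "spearman")
  kept <- character()
  drops <- list()
  for (f in members) {
    if (length(kept)) {
      r <- rho[f, kept]
      bad <- which(abs(r) > rho_max)
      if (length(bad)) {
        drops[[length(drops) + 1L]] <-
          data.frame(kept = kept[bad[1]], dropped = f,
                     spearman_rho = unname(r[bad[1]]))
        next
      }
    }
    kept <- c(kept, f)
  }
  structure(list(members = kept,
                 dropped_pairs = if (length(drops)) do.call(rbind, drops)
                                 else data.frame(kept = character(),
                                                 dropped = character(),
                                                 spearman_rho = numeric())),
            class = "fusion_set")
}

#' @export
print.fusion_set <- function(x, ...) {
  cat(sprintf("<fusion_set> %d member(s), %d dropped by correlation pruning\n",
              length(x$members), nrow(x$dropped_pairs)))
  invisible(x)
}
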