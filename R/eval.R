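#' Stratified train / internal-test split
#'
#' Splits the training pool 8:2 by stratified random sampling: the test size
#' is `ceil(test_frac * n)`, apportioned across classes by largest remainder
#' of the class-proportional quotas; within a class, membership comes from a
#' seeded shuffle.  Cases tagged `external` never enter train or internal
#' test.
#'
#' @param labels integer class labels (0/1/2) for all cases.
#' @param cohort_tags optional tags; `"external"` forces `external_test`.
#' @param test_frac internal test fraction (default 0.2).
#' @param seed split seed.
#' @return Factor with levels `train`, `internal_test`, `external_test`,
#'   one per case, in input order.
#' @export
stratified_split <- function(labels, cohort_tags = NULL, test_frac = 0.2,
                             seed = 0L) {
  n_all <- length(labels)
  ext <- if (is.null(cohort_tags)) rep(FALSE, n_all) else
    cohort_tags == "external"
  out <- rep("train", n_all)
  out[ext] <- "external_test"
  pool <- which(!ext)
  lab <- labels[pool]
  n <- length(pool)
  classes <- sort(unique(lab))
  if (any(table(lab) < 2)) stop("every class needs at least 2 pool cases")
  n_test <- ceiling(test_frac * n)
  quota <- n_test * as.vector(table(factor(lab, classes))) / n
  alloc <- largest_remainder(quota, n_test)
  run_seeded(seed, {
    for (ci in seq_along(classes)) {
      idx <- pool[lab == classes[ci]]
      take <- sample(idx, alloc[ci])
      out[take] <- "internal_test"
    }
  })
  factor(out, levels = c("train", "internal_test", "external_test"))
}

# Rank-statistic (Mann-Whitney) AUC with tie correction.
auc_binary <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Core multiclass metrics from a score matrix.
multiclass_metrics <- function(P, y, classes = 0:2) {
  pred <- classes[max.col(P, ties.method = "first")]
  cm <- table(factor(y, classes), factor(pred, classes))
  n <- length(y)
  acc <- sum(diag(cm)) / n
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- classes %in% y
  aucs <- vapply(seq_along(classes), function(ci)
    auc_binary(P[, ci], y == classes[ci]), 0)
  # micro: pool all (case, class) one-vs-rest indicator/score pairs
  micro <- auc_binary(as.vector(P),
                      as.vector(outer(y, classes, "==")))
  list(confusion_matrix = unclass(cm), accuracy = acc,
       precision = mean(prec[present]), recall = mean(rec[present]),
       f1 = mean(f1[present]),
       auc_per_class = stats::setNames(aucs, paste0("class", classes)),
       macro_auc = mean(aucs[present], na.rm = TRUE), micro_auc = micro,
       present = present)
}

#' Evaluate a model (or score matrix) on one data split
#'
#' Produces the full multiclass report: confusion matrix, accuracy,
#' macro-averaged precision/recall/F1, per-class one-vs-rest AUC, macro- and
#' micro-AUC, and a stratified case-level bootstrap percentile 95% CI for
#' the macro-AUC.  A class absent from the evaluation set has undefined
#' one-vs-rest AUC; it is reported as `NA` and the macro average covers the
#' present classes, with a warning.
#'
#' @param model a `dlr_model`, or a ready score matrix (`n x 3`).
#' @param X feature matrix (ignored when `model` is a score matrix).
#' @param y integer labels (0/1/2).
#' @param n_bootstrap bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @param split_id optional identifier tying reports to one split (checked
#'   by [compare_models]).
#' @param model_name label carried into rankings.
#' @return An `eval_report` list.
#' @export
evaluate <- function(model, X = NULL, y, n_bootstrap = 2000L, seed = 0L,
                     split_id = NULL, model_name = NULL) {
  P <- if (inherits(model, "dlr_model")) predict_proba(model, X) else
    as.matrix(model)
  stopifnot(nrow(P) == length(y), ncol(P) == 3)
  classes <- 0:2
  if (!all(y %in% classes)) stop("labels must be in {0, 1, 2}")
  m <- multiclass_metrics(P, y, classes)
  if (!all(m$present))
    warning("class(es) ", paste(classes[!m$present], collapse = ", "),
            " absent from evaluation set; macro metrics cover present classes")
  boots <- run_seeded(seed, {
    by_class <- split(seq_along(y), y)
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- unlist(lapply(by_class, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      mb <- multiclass_metrics(P[idx, , drop = FALSE], y[idx], classes)
      mb$macro_auc
    }, 0)
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(list(model_name = model_name, split_id = split_id,
                 confusion_matrix = m$confusion_matrix,
                 accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1,
                 auc_per_class = m$auc_per_class,
                 macro_auc = m$macro_auc, micro_auc = m$micro_auc,
                 ci_95 = c(low = ci[1], high = ci[2]),
                 n_bootstrap = n_bootstrap, n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report>%s n=%d  accuracy %.3f  macro-AUC %.3f ",
                     "(95%% CI %.3f-%.3f)  micro-AUC %.3f  F1 %.3f\n"),
              if (is.null(x$model_name)) "" else paste0(" ", x$model_name),
              x$n, x$accuracy, x$macro_auc, x$ci_95["low"], x$ci_95["high"],
              x$micro_auc, x$f1))
  print(x$confusion_matrix)
  invisible(x)
}

#' Rank evaluation reports
#'
#' Sorts reports by macro-AUC (ties broken by accuracy, then F1) and emits
#' the model-inventory summary table.  All reports must come from the same
#' split.
#'
#' @param reports list of `eval_report`s.
#' @return data.frame, best model first.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 1) stop("no reports")
  sids <- unique(vapply(reports, function(r)
    if (is.null(r$split_id)) NA_character_ else r$split_id, ""))
  if (length(sids) > 1)
    stop("reports come from different splits: ",
         paste(sids, collapse = " vs "))
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = if (is.null(r$model_name)) "model" else r$model_name,
               macro_auc = r$macro_auc, ci_low = r$ci_95[["low"]],
               ci_high = r$ci_95[["high"]], micro_auc = r$micro_auc,
               accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, n = r$n)
  }))
  tab[order(-tab$macro_auc, -tab$accuracy, -tab$f1), , drop = FALSE]
}
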