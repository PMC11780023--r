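#' Experiment configuration
#'
#' One config drives the whole experiment: data source, preprocessing,
#' radiomics extraction, embedding backends, selection, classifier and
#' evaluation.  Every random stage has an explicit seed, and the config is
#' serialized (JSON) alongside the outputs.
#'
#' @param spec a [phantom_spec] (simulated cohort), or `NULL` when
#'   `manifest` is given.
#' @param manifest path to a cohort manifest CSV (see [ingest_manifest]).
#' @param radiomics a [radiomics_config].
#' @param backends list of [backend_spec]s (default one pseudo backend).
#' @param classifier one of `"svm"`, `"lr"`, `"rf"`, `"dt"`.
#' @param phases feature blocks to model (default AP, PP, combined).
#' @param target_mm resampling target.
#' @param icc_threshold reproducibility cutoff (features kept when both
#'   inter- and intra-reader ICC reach it).
#' @param rho_max fusion Spearman pruning ceiling.
#' @param test_frac internal test fraction.
#' @param n_bootstrap bootstrap replicates per evaluation.
#' @param split_seed,lasso_seed,boot_seed,clf_seed stage seeds.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec(), manifest = NULL,
                              radiomics = radiomics_config(),
                              backends = list(backend_spec("pseudo")),
                              classifier = "lr",
                              phases = c("AP", "PP", "combined"),
                              target_mm = c(1, 1, 1),
                              icc_threshold = 0.8, rho_max = 0.9,
                              test_frac = 0.2, n_bootstrap = 2000L,
                              split_seed = 101L, lasso_seed = 202L,
                              boot_seed = 303L, clf_seed = 404L) {
  if (is.null(spec) && is.null(manifest))
    stop("either a phantom spec or a manifest path is required")
  if (inherits(backends, "backend_spec")) backends <- list(backends)
  structure(as.list(environment()), class = "experiment_config")
}

#' Read and validate a cohort manifest
#'
#' The manifest CSV must have columns `case_id`, `cohort_tag`, `label`,
#' `ap_path`, `pp_path`, `mask_path` (paths relative to the manifest's
#' directory or absolute).  All validation problems are reported together,
#' itemized by row.
#'
#' @param path manifest CSV path.
#' @return List of case records as produced by [generate_cohort].
#' @export
ingest_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("case_id", "cohort_tag", "label", "ap_path", "pp_path", "mask_path")
  miss <- setdiff(req, colnames(man))
  if (length(miss))
    stop("manifest lacks required column(s): ", paste(miss, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  errs <- character()
  cases <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    if (!row$label %in% 0:2) {
      errs <- c(errs, sprintf("row %d (%s): label %s not in {0,1,2}",
                              i, row$case_id, row$label))
      next
    }
    paths <- resolve(c(row$ap_path, row$pp_path, row$mask_path))
    gone <- !file.exists(paths)
    if (any(gone)) {
      errs <- c(errs, sprintf("row %d (%s): missing file(s) %s", i,
                              row$case_id, paste(paths[gone], collapse = ", ")))
      next
    }
    ap <- read_nifti(paths[1]); pp <- read_nifti(paths[2])
    mk <- as_mask(read_nifti(paths[3]))
    shape_ok <- tryCatch({
      check_pair(ap, mk); check_pair(pp, mk); TRUE
    }, error = function(e) FALSE)
    if (!shape_ok) {
      errs <- c(errs, sprintf("row %d (%s): image/mask grid mismatch",
                              i, row$case_id))
      next
    }
    if (mask_count(mk) == 0) {
      errs <- c(errs, sprintf("row %d (%s): empty mask", i, row$case_id))
      next
    }
    cases[[i]] <- structure(list(case_id = row$case_id,
                                 cohort_tag = row$cohort_tag,
                                 label = as.integer(row$label),
                                 ap_volume = ap, pp_volume = pp, mask = mk),
                            class = "case_record")
  }
  if (length(errs))
    stop("manifest validation failed:\n  ", paste(errs, collapse = "\n  "))
  cases
}

# Intercept-only fallback when selection is empty: predicts the training
# class frequencies.
prior_model <- function(y) {
  structure(list(type = "prior",
                 fit = as.vector(table(factor(y, 0:2)) / length(y)),
                 levels = as.character(0:2), features = NULL),
            class = "dlr_model")
}

#' Run the full experiment
#'
#' Orchestrates simulate/ingest, preprocessing, radiomics extraction, the
#' ICC reproducibility filter (when reader masks exist), Max-ROI slice
#' extraction and deep embedding, per-modality z-score + LASSO selection,
#' fusion with Spearman pruning, classifier training, and evaluation of the
#' full model inventory — per phase: one radiomics model, one DTL model per
#' backend, one fusion model per backend — on the internal (and, if
#' present, external) test sets.
#'
#' @param config an [experiment_config].
#' @param out_dir optional directory: persists the summary CSV, per-model
#'   reports (JSON), selected feature lists and the config.
#' @return List with `summary` (ranking data.frame over internal-test
#'   reports), `reports` (all `eval_report`s), `split`, `selected`,
#'   `icc` (filter table or NULL), and the feature tables.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cases <- if (!is.null(config$manifest)) ingest_manifest(config$manifest)
           else generate_cohort(config$spec)
  labels <- vapply(cases, function(cc) cc$label, 0L)
  tags <- vapply(cases, function(cc) cc$cohort_tag, "")
  ids <- vapply(cases, function(cc) cc$case_id, "")
  split <- stratified_split(labels, tags, config$test_frac, config$split_seed)
  names(split) <- ids

  feat_rad <- radiomics_table(cases, config$radiomics, config$target_mm)

  # reproducibility filter on the cases that carry reader masks
  icc_tab <- NULL
  rd_ids <- ids[vapply(cases, function(cc) !is.null(cc$reader2_mask), TRUE)]
  if (length(rd_ids) >= 10) {
    r1 <- feat_rad[rd_ids, , drop = FALSE]
    r2 <- radiomics_table(cases, config$radiomics, config$target_mm,
                          mask_field = "reader2_mask", cases_subset = rd_ids)
    rr <- radiomics_table(cases, config$radiomics, config$target_mm,
                          mask_field = "reader1_repeat_mask",
                          cases_subset = rd_ids)
    icc_tab <- icc_filter(r1, r2[rd_ids, , drop = FALSE],
                          rr[rd_ids, , drop = FALSE], config$icc_threshold)
    keep <- icc_tab$feature[icc_tab$retained]
    # never drop below a usable feature set: shape features are
    # delineation-sensitive too, but the filter decides
    feat_rad <- feat_rad[, keep, drop = FALSE]
  }

  stacks <- cohort_stacks(cases, target_mm = config$target_mm)
  feat_dtl <- lapply(config$backends, function(b)
    deep_feature_table(stacks, b))
  names(feat_dtl) <- vapply(config$backends, function(b) b$name, "")

  tr <- names(split)[split == "train"]
  te <- names(split)[split == "internal_test"]
  ex <- names(split)[split == "external_test"]
  ytr <- labels[match(tr, ids)]
  split_id <- paste0("split", config$split_seed, "n", length(ids))

  phase_cols <- function(tab, phase) {
    if (phase == "combined") colnames(tab)
    else grep(paste0("^", phase, "_"), colnames(tab), value = TRUE)
  }

  reports <- list(); selected <- list()
  fit_block <- function(tab, phase, model_name, pre_selected = NULL) {
    cols <- phase_cols(tab, phase)
    z <- withCallingHandlers(
      zscore(tab[tr, cols, drop = FALSE], tab[, cols, drop = FALSE]),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pre_selected)) {
      nf <- min(5L, min(table(ytr)))     # tiny cohorts: shrink the CV folds
      if (nf < 3L) {                     # below glmnet's CV minimum
        warning(model_name, ": too few cases per class for CV selection; ",
                "falling back to the intercept-only prior")
        keep <- character()
      } else {
        sel <- lasso_select(z$train, ytr, n_folds = nf,
                            seed = config$lasso_seed)
        keep <- sel$selected_names
      }
    } else {
      keep <- intersect(pre_selected, colnames(z$train))
    }
    selected[[model_name]] <<- keep
    model <- if (!length(keep)) {
      warning(model_name, ": empty selection; intercept-only fallback")
      prior_model(ytr)
    } else {
      train_model(list(classifier = config$classifier,
                       seed = config$clf_seed),
                  z$newdata[tr, keep, drop = FALSE], ytr)
    }
    out <- list()
    for (part in list(c("internal", "te"), c("external", "ex"))) {
      idx <- get(part[2])
      if (!length(idx)) next
      X <- z$newdata[idx, keep, drop = FALSE]
      P <- if (model$type == "prior")
        matrix(model$fit, length(idx), 3, byrow = TRUE)
      else predict_proba(model, X)
      out[[part[1]]] <- evaluate(P, y = labels[match(idx, ids)],
                                 n_bootstrap = config$n_bootstrap,
                                 seed = config$boot_seed,
                                 split_id = split_id,
                                 model_name = paste0(model_name, "-",
                                                     part[1]))
    }
    out
  }

  for (ph in config$phases) {
    reports[[paste0("radiomics-", ph)]] <-
      fit_block(feat_rad, ph, paste0("radiomics-", ph))
    for (bn in names(feat_dtl)) {
      reports[[paste0("dtl-", bn, "-", ph)]] <-
        fit_block(feat_dtl[[bn]], ph, paste0("dtl-", bn, "-", ph))
      # fusion: per-modality selections, concatenated, Spearman-pruned
      sel_rad <- selected[[paste0("radiomics-", ph)]]
      sel_dtl <- selected[[paste0("dtl-", bn, "-", ph)]]
      both <- cbind(feat_rad, feat_dtl[[bn]])
      fu <- fuse_and_prune(sel_rad, sel_dtl, both[tr, , drop = FALSE],
                           config$rho_max)
      reports[[paste0("fusion-", bn, "-", ph)]] <-
        fit_block(both, "combined", paste0("fusion-", bn, "-", ph),
                  pre_selected = fu$members)
    }
  }

  internal <- lapply(reports, function(r) r$internal)
  summary_tab <- compare_models(internal[!vapply(internal, is.null, TRUE)])
  external <- Filter(Negate(is.null), lapply(reports, function(r) r$external))
  if (length(external)) {
    ext_tab <- compare_models(external)
    summary_tab <- rbind(summary_tab, ext_tab)
  }
  rownames(summary_tab) <- NULL

  result <- list(summary = summary_tab, reports = reports, split = split,
                 selected = selected, icc = icc_tab,
                 features_radiomics = feat_rad, features_deep = feat_dtl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) lapply(Filter(Negate(is.null), r),
        function(e) unclass(e))),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(serialize_config(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(model = rep(names(selected),
                             vapply(selected, length, 0L)),
                 feature = unlist(selected, use.names = FALSE)),
      file.path(out_dir, "selected_features.csv"), row.names = FALSE)
    if (!is.null(icc_tab))
      utils::write.csv(icc_tab, file.path(out_dir, "icc_filter.csv"),
                       row.names = FALSE)
    write_feature_table(feat_rad, file.path(out_dir, "features_radiomics.csv"),
                        config$radiomics)
    for (bn in names(feat_dtl))
      write_feature_table(feat_dtl[[bn]],
                          file.path(out_dir, sprintf("features_dtl_%s.csv", bn)))
  }
  result
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$spec <- if (!is.null(cfg$spec)) unclass(cfg$spec)
  cfg$radiomics <- unclass(cfg$radiomics)
  cfg$backends <- lapply(cfg$backends, unclass)
  cfg
}
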