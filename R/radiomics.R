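#' Radiomics extraction configuration
#'
#' Bundles the knobs of the feature extractor.  The default configuration
#' (all 18 derived image types, bin width 5, GLCM distance 1, GLDM alpha 0)
#' emits exactly 1781 named features per phase: 14 shape + 19 images x 93
#' intensity/texture features.
#'
#' @param filters derived-image filter specs (see [default_filters]); use
#'   `list()` for the reduced original-image-only configuration
#'   (107 features).
#' @param bin_width gray-level discretization width (default 5).
#' @param glcm_distance co-occurrence offset distance (default 1).
#' @param gldm_alpha dependence threshold (default 0).
#' @param pad_voxels context padding kept around the mask bounding box before
#'   filtering (default 12, enough for the largest default LoG kernel).
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(filters = default_filters(), bin_width = 5,
                             glcm_distance = 1L, gldm_alpha = 0L,
                             pad_voxels = 12L) {
  stopifnot(bin_width > 0, glcm_distance >= 1, gldm_alpha >= 0)
  structure(list(filters = filters, bin_width = bin_width,
                 glcm_distance = as.integer(glcm_distance),
                 gldm_alpha = as.integer(gldm_alpha),
                 pad_voxels = as.integer(pad_voxels)),
            class = "radiomics_config")
}

#' Extract the radiomics feature vector for one volume + mask
#'
#' Computes 14 shape features on the mask, then, for the original image and
#' every filter-derived image, 93 features: 18 first-order, 24 GLCM, 16
#' GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM.  GLCM/GLRLM features are averaged
#' over the 13 unique 3-D directions.  Feature names are
#' `"<image>_<family>_<Feature>"`, identical and identically ordered across
#' cases.
#'
#' @param vol a preprocessed [volume] (see [preprocess_volume]).
#' @param mask the paired binary mask [volume].
#' @param config a [radiomics_config].
#' @return Named numeric vector (length 1781 under the default config).
#' @export
extract_features <- function(vol, mask, config = radiomics_config()) {
  stopifnot(is_volume(vol), is_volume(mask),
            inherits(config, "radiomics_config"))
  check_pair(vol, mask)
  if (mask_count(mask) == 0) stop("mask is empty")
  cp <- crop_case(vol, mask, config$pad_voxels)
  out <- shape_features(cp$mask)
  names(out) <- paste0("original_shape_", names(out))
  bank <- filter_bank(cp$vol, config$filters)
  inm <- cp$mask$data != 0
  n_vox <- sum(inm)
  voxvol <- prod(cp$vol$spacing_mm)
  for (label in names(bank)) {
    img <- bank[[label]]
    dv <- discretize(img, cp$mask, config$bin_width)
    x <- img$data[inm]
    fo <- firstorder_features(x, dv$levels[inm], voxvol)
    gl <- glcm_features(compute_glcm(dv, distance = config$glcm_distance))
    rl <- glrlm_features(compute_glrlm(dv), n_vox)
    sz <- glszm_features(compute_glszm(dv)$values, n_vox)
    dmf <- gldm_features(compute_gldm(dv, alpha = config$gldm_alpha)$values)
    nt <- ngtdm_features(compute_ngtdm(dv)$values)
    block <- c(stats::setNames(fo, paste0(label, "_firstorder_", names(fo))),
               stats::setNames(gl, paste0(label, "_glcm_", names(gl))),
               stats::setNames(rl, paste0(label, "_glrlm_", names(rl))),
               stats::setNames(sz, paste0(label, "_glszm_", names(sz))),
               stats::setNames(dmf, paste0(label, "_gldm_", names(dmf))),
               stats::setNames(nt, paste0(label, "_ngtdm_", names(nt))))
    out <- c(out, block)
  }
  out
}

# Crop image and mask to the mask bounding box plus filter context padding.
crop_case <- function(vol, mask, pad) {
  ix <- which(mask$data != 0, arr.ind = TRUE)
  d <- dim(mask$data)
  lo <- pmax(apply(ix, 2, min) - pad, 1L)
  hi <- pmin(apply(ix, 2, max) + pad, d)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  v <- vol; v$data <- sub(vol$data)
  m <- mask; m$data <- sub(mask$data)
  orig_shift <- (lo - 1) * vol$spacing_mm
  v$origin_mm <- vol$origin_mm + orig_shift
  m$origin_mm <- v$origin_mm
  list(vol = v, mask = m)
}

#' Write a feature table as CSV with a JSON provenance sidecar
#'
#' One row per case, first column `case_id`; the sidecar (`<path>.json`)
#' records the extraction configuration (filters, bin width, distances).
#'
#' @param tab feature data.frame (row names = case ids).
#' @param path output CSV path.
#' @param config the [radiomics_config] (or any list) that produced it.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path, config = NULL) {
  out <- cbind(case_id = rownames(tab), tab)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Radiomics feature table for a cohort
#'
#' Runs preprocessing and [extract_features] for every case and phase and
#' returns one row per case with phase-prefixed columns (`AP_`, `PP_`).
#' Cases whose mask empties after resampling are dropped with a warning.
#'
#' @param cases list of case records (see [generate_cohort] /
#'   [ingest_manifest]).
#' @param config a [radiomics_config].
#' @param target_mm resampling target passed to [preprocess_volume].
#' @param mask_field which mask to delineate with (default `"mask"`;
#'   `"reader2_mask"` / `"reader1_repeat_mask"` for reproducibility runs).
#' @param cases_subset optional case ids to restrict to.
#' @return A data.frame of features, row names = case ids.
#' @export
radiomics_table <- function(cases, config = radiomics_config(),
                            target_mm = c(1, 1, 1), mask_field = "mask",
                            cases_subset = NULL) {
  if (!is.null(cases_subset))
    cases <- cases[vapply(cases, function(cc) cc$case_id %in% cases_subset,
                          TRUE)]
  rows <- list()
  for (cc in cases) {
    msk <- cc[[mask_field]]
    if (is.null(msk)) stop("case ", cc$case_id, " has no ", mask_field)
    feats <- tryCatch({
      one_phase <- function(fld, prefix) {
        pp <- preprocess_volume(cc[[fld]], msk, target_mm = target_mm)
        if (mask_count(pp$mask) == 0) stop("mask empty after resampling")
        fv <- extract_features(pp$vol, pp$mask, config)
        stats::setNames(fv, paste0(prefix, "_", names(fv)))
      }
      c(one_phase("ap_volume", "AP"), one_phase("pp_volume", "PP"))
    }, error = function(e) {
      warning("case ", cc$case_id, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(feats)) rows[[cc$case_id]] <- feats
  }
  if (!length(rows)) stop("no cases could be extracted")
  nm <- names(rows[[1]])
  bad <- vapply(rows, function(r) !identical(names(r), nm), TRUE)
  if (any(bad)) stop("inconsistent feature names across cases")
  as.data.frame(do.call(rbind, rows))
}
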