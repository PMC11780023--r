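#' Select the Max-ROI axial slice
#'
#' Returns the index (1-based, third grid axis) of the axial slice with the
#' largest tumor cross-sectional area; ties break to the lowest index.
#'
#' @param mask a binary [volume].
#' @return Integer slice index.
#' @export
select_max_roi <- function(mask) {
  stopifnot(is_volume(mask))
  areas <- apply(mask$data != 0, 3, sum)
  if (sum(areas) == 0) stop("mask is empty")
  which.max(areas)                        # first maximum = lowest index
}

#' Extract the five Max-ROI tumor crops for one case-phase
#'
#' Takes the Max-ROI slice and its -2, -1, +1, +2 axial neighbours, and
#' crops each to the minimum bounding rectangle of the tumor in that slice.
#' An offset slice without tumor (thin lesion) is substituted by the nearest
#' tumor-bearing slice in that direction, with a warning — the 5-image
#' contract always holds.
#'
#' @param vol the (preprocessed) image [volume].
#' @param mask the paired binary mask.
#' @param case_id,phase carried into the result for bookkeeping.
#' @return A `slice_stack`: `offsets` (-2..2), `slice_index` (per offset,
#'   after substitution), `images` (5 cropped matrices) and `crop_boxes`
#'   (0-based half-open `row_min, row_max, col_min, col_max`).
#' @export
extract_stack <- function(vol, mask, case_id = "case", phase = "AP") {
  stopifnot(is_volume(vol), is_volume(mask))
  check_pair(vol, mask)
  areas <- apply(mask$data != 0, 3, sum)
  if (sum(areas) == 0) stop("mask is empty")
  nz <- dim(mask$data)[3]
  z0 <- which.max(areas)
  offsets <- -2:2
  zs <- integer(5)
  for (i in seq_along(offsets)) {
    z <- z0 + offsets[i]
    if (z < 1 || z > nz || areas[z] == 0) {
      # walk back toward the Max-ROI slice until tumor is found
      step <- if (offsets[i] < 0) 1L else -1L
      z <- min(max(z, 1L), nz)
      while (areas[z] == 0 && z != z0) z <- z + step
      warning(sprintf("case %s %s: offset %+d slice has no tumor; using slice %d",
                      case_id, phase, offsets[i], z))
    }
    zs[i] <- z
  }
  images <- vector("list", 5)
  boxes <- matrix(NA_integer_, 5, 4,
                  dimnames = list(NULL, c("row_min", "row_max",
                                          "col_min", "col_max")))
  for (i in seq_along(zs)) {
    msl <- mask$data[, , zs[i]] != 0
    rr <- range(which(apply(msl, 1, any)))
    cc <- range(which(apply(msl, 2, any)))
    images[[i]] <- vol$data[rr[1]:rr[2], cc[1]:cc[2], zs[i], drop = TRUE]
    if (!is.matrix(images[[i]]))
      images[[i]] <- matrix(images[[i]], rr[2] - rr[1] + 1, cc[2] - cc[1] + 1)
    boxes[i, ] <- c(rr[1] - 1L, rr[2], cc[1] - 1L, cc[2])  # 0-based half-open
  }
  structure(list(case_id = case_id, phase = phase, offsets = offsets,
                 slice_index = zs, images = images, crop_boxes = boxes),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %s %s: 5 crops, shapes %s\n", x$case_id, x$phase,
              paste(vapply(x$images, function(m)
                paste(dim(m), collapse = "x"), ""), collapse = ", ")))
  invisible(x)
}

#' Extract slice stacks for a whole cohort
#'
#' @param cases list of case records.
#' @param phases which phases to process (default both).
#' @param preprocess run [preprocess_volume] first (crops are taken from
#'   normalized/equalized volumes, matching the modelling pipeline).
#' @param target_mm resampling target when preprocessing.
#' @return Named list of `slice_stack`s, names `"<case>_<phase>"`.
#' @export
cohort_stacks <- function(cases, phases = c("AP", "PP"), preprocess = TRUE,
                          target_mm = c(1, 1, 1)) {
  out <- list()
  for (cc in cases) {
    for (ph in phases) {
      fld <- if (ph == "AP") "ap_volume" else "pp_volume"
      v <- cc[[fld]]; m <- cc$mask
      if (preprocess) {
        pp <- preprocess_volume(v, m, target_mm = target_mm)
        v <- pp$vol; m <- pp$mask
      }
      out[[paste(cc$case_id, ph, sep = "_")]] <-
        extract_stack(v, m, cc$case_id, ph)
    }
  }
  out
}

#' Export slice stacks as 8-bit grayscale PNGs
#'
#' Writes one PNG per crop, named `{case}_{phase}_{offset}.png`, plus a
#' `slices_manifest.csv` linking images to cases.  Intensities are mapped
#' from `[0, 255]` to 8-bit gray.
#'
#' @param stacks list of `slice_stack`s (see [cohort_stacks]).
#' @param dir output directory.
#' @return The manifest data.frame, invisibly.
#' @export
export_stacks <- function(stacks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (st in stacks) {
    for (i in seq_along(st$offsets)) {
      off <- st$offsets[i]
      fn <- sprintf("%s_%s_%+d.png", st$case_id, st$phase, off)
      img <- pmin(pmax(st$images[[i]] / 255, 0), 1)
      png::writePNG(img, file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(case_id = st$case_id, phase = st$phase, offset = off,
                   slice_index = st$slice_index[i], file = fn)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "slices_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
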