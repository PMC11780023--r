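#' Phantom cohort specification
#'
#' Describes a synthetic dual-phase cohort with planted, tunable class
#' structure along the axes that distinguish the three lesion classes in
#' dual-phase liver MRI: capsule prevalence, margin irregularity,
#' arterial/portal-venous enhancement pattern, and internal texture
#' correlation length.  Per-class vectors are ordered (HCC, DPHCC, ICC) =
#' labels (0, 1, 2).  Setting all per-class fields equal across classes
#' defines the null spec (no class signal).
#'
#' The defaults are the documented "strong-effect" world: a hypervascular,
#' encapsulated, smooth-margined HCC with portal-venous washout; a
#' capsule-free, irregular-margined DPHCC with intermediate enhancement; and
#' a hypovascular ICC with progressive portal-venous enhancement and coarser
#' internal texture.
#'
#' @param n_cases number of cases.
#' @param class_probs 3-vector of class proportions (sums to 1).
#' @param balanced exact largest-remainder apportionment instead of a
#'   multinomial draw.
#' @param grid_shape 3 positive integers, native grid in voxels.
#' @param voxel_spacing_mm 3 positive reals (mm).
#' @param lesion_radius_mm length-2 range; radii are drawn uniformly.
#' @param margin_irregularity per-class boundary perturbation amplitude (mm).
#' @param capsule_prob per-class probability of a hyperintense rim.
#' @param enhancement_ap,enhancement_pp per-class lesion-minus-background
#'   mean intensity offsets.
#' @param texture_corr_len_mm per-class correlation length of the interior
#'   Gaussian texture field.
#' @param texture_sd interior texture field standard deviation.
#' @param background_mean background organ intensity.
#' @param capsule_intensity added rim intensity.
#' @param noise_sd additive white acquisition noise SD.
#' @param reader_jitter_mm mask perturbation scale for the two-reader ICC
#'   simulation (0 disables reader masks' divergence).
#' @param n_reader_cases how many cases get reader2 / repeat masks.
#' @param external_frac fraction of cases tagged `external` (held-out
#'   centres).
#' @param seed integer master seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cases = 30L,
                         class_probs = c(1, 1, 1) / 3,
                         balanced = TRUE,
                         grid_shape = c(32L, 32L, 24L),
                         voxel_spacing_mm = c(1, 1, 2),
                         lesion_radius_mm = c(6, 9),
                         margin_irregularity = c(0.4, 2.2, 1.2),
                         capsule_prob = c(0.85, 0.1, 0.1),
                         enhancement_ap = c(55, 32, 10),
                         enhancement_pp = c(-12, 2, 26),
                         texture_corr_len_mm = c(2, 3.5, 5.5),
                         texture_sd = 12,
                         background_mean = 100,
                         capsule_intensity = 28,
                         noise_sd = 5,
                         reader_jitter_mm = 1,
                         n_reader_cases = 0L,
                         external_frac = 0,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0))
      stop("class_probs must be non-negative and sum to 1")
    if (length(grid_shape) != 3 || any(grid_shape < 4))
      stop("grid_shape must be 3 positive integers")
    if (any(voxel_spacing_mm <= 0)) stop("voxel spacing must be positive")
    if (length(lesion_radius_mm) != 2 || any(lesion_radius_mm <= 0) ||
        diff(lesion_radius_mm) < 0)
      stop("lesion_radius_mm must be an increasing positive range")
    for (nm in c("margin_irregularity", "capsule_prob", "enhancement_ap",
                 "enhancement_pp", "texture_corr_len_mm"))
      if (length(get(nm)) != 3) stop(nm, " must have one value per class")
    if (any(margin_irregularity < 0) || noise_sd < 0 || reader_jitter_mm < 0)
      stop("amplitudes must be non-negative")
    extent <- grid_shape * voxel_spacing_mm
    need <- 2 * (max(lesion_radius_mm) + max(margin_irregularity) + 3)
    if (any(extent < need))
      stop("grid too small to contain the lesion radius range ",
           "(need >= ", round(need, 1), " mm per axis)")
  })
  invisible(spec)
}

#' The null phantom spec
#'
#' Same world as [phantom_spec] but with every per-class field equal across
#' classes, so no image property carries label information.
#'
#' @param ... overrides passed to [phantom_spec].
#' @return A `phantom_spec`.
#' @export
phantom_spec_null <- function(...) {
  phantom_spec(margin_irregularity = rep(1, 3),
               capsule_prob = rep(0.3, 3),
               enhancement_ap = rep(30, 3),
               enhancement_pp = rep(10, 3),
               texture_corr_len_mm = rep(3.5, 3),
               ...)
}

#' Generate a phantom cohort
#'
#' Draws class labels (multinomial, or exact largest-remainder apportionment
#' when `spec$balanced`), then generates each case with [generate_case].
#' Identical spec + seed reproduce bit-identical voxel data.  The first
#' `n_reader_cases` cases additionally carry a second reader's mask and a
#' first-reader repeat mask (both produced by [perturb_mask]) for the ICC
#' reproducibility filter.
#'
#' @param spec a [phantom_spec].
#' @return List of case records: `case_id`, `cohort_tag`, `label`,
#'   `ap_volume`, `pp_volume`, `mask`, and optional `reader2_mask`,
#'   `reader1_repeat_mask`.
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  run_seeded(spec$seed, {
    n <- spec$n_cases
    labels <- if (isTRUE(spec$balanced)) {
      counts <- largest_remainder(spec$class_probs * n, n)
      sample(rep(0:2, counts))
    } else {
      sample(0:2, n, replace = TRUE, prob = spec$class_probs)
    }
    n_ext <- round(spec$external_frac * n)
    tags <- rep("train_pool", n)
    if (n_ext > 0) tags[sample.int(n, n_ext)] <- "external"
    case_seeds <- sample.int(1e9, n)
    lapply(seq_len(n), function(i) {
      rec <- generate_case(labels[i], spec, seed = case_seeds[i],
                           with_readers = i <= spec$n_reader_cases)
      rec$case_id <- sprintf("case_%03d", i)
      rec$cohort_tag <- tags[i]
      rec
    })
  })
}

# Largest-remainder apportionment of `total` slots to quotas.
largest_remainder <- function(quota, total) {
  fl <- floor(quota)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(quota - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Generate one phantom case
#'
#' The lesion is a sphere of sampled radius whose boundary is perturbed by a
#' smooth random field of the class's margin-irregularity amplitude; with the
#' class's capsule probability a thin hyperintense rim is added just outside
#' the mask.  The interior is the class's AP/PP mean enhancement plus a
#' correlated Gaussian texture field (mean-centred over the interior, so the
#' planted mean offset is exact up to white noise); background is a
#' homogeneous organ compartment.  White acquisition noise is added
#' everywhere.
#'
#' @param label class label in `{0, 1, 2}` = (HCC, DPHCC, ICC).
#' @param spec a [phantom_spec].
#' @param seed per-case seed.
#' @param with_readers also simulate reader2 / reader1-repeat masks.
#' @return A case record (see [generate_cohort]).
#' @export
generate_case <- function(label, spec, seed = 1L, with_readers = FALSE) {
  stopifnot(label %in% 0:2)
  validate_phantom_spec(spec)
  k <- label + 1L
  run_seeded(seed, {
    d <- spec$grid_shape
    sp <- spec$voxel_spacing_mm
    extent <- d * sp
    r <- stats::runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
    amp <- spec$margin_irregularity[k]
    margin <- r + amp + 2
    if (any(extent / 2 < margin))
      stop("grid too small to contain a lesion of radius ", round(r, 1), " mm")
    ctr <- extent / 2 + stats::runif(3, -1.5, 1.5)
    # voxel-centre coordinates (mm)
    ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 0.5) * sp[a]))
    dist2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                   (ax[[3]] - ctr[3])^2, "+")
    dist <- sqrt(dist2)
    # smooth unit-SD boundary perturbation field
    gfield <- function(corr_mm) {
      w <- array(stats::rnorm(prod(d)), d)
      s <- gauss_smooth(w, (corr_mm / 2) / sp)
      s / stats::sd(s)
    }
    wob <- if (amp > 0) gfield(6) else array(0, d)
    radius_map <- r + amp * wob
    mask <- (dist <= radius_map) * 1
    if (sum(mask) == 0) stop("degenerate lesion (empty mask)")
    has_capsule <- stats::runif(1) < spec$capsule_prob[k]
    ring <- mask == 0 & dist <= radius_map + 1.5 * min(sp[1:2])
    tex <- gfield(spec$texture_corr_len_mm[k]) * spec$texture_sd
    tex <- tex - mean(tex[mask == 1])          # planted offset is exact
    make_phase <- function(enh) {
      img <- array(spec$background_mean, d)
      img <- img + mask * (enh + tex)
      if (has_capsule) img[ring] <- img[ring] + spec$capsule_intensity
      img + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    }
    apv <- volume(make_phase(spec$enhancement_ap[k]), sp)
    ppv <- volume(make_phase(spec$enhancement_pp[k]), sp)
    mvol <- volume(mask, sp)
    rec <- list(case_id = NA_character_, cohort_tag = "train_pool",
                label = label, ap_volume = apv, pp_volume = ppv, mask = mvol)
    if (with_readers) {
      jseed <- sample.int(1e9, 2)
      rec$reader2_mask <- perturb_mask(mvol, spec$reader_jitter_mm, jseed[1])
      rec$reader1_repeat_mask <- perturb_mask(mvol, spec$reader_jitter_mm,
                                              jseed[2])
    }
    class(rec) <- "case_record"
    rec
  })
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s label=%d (%s) tag=%s, %d mask voxels\n",
              x$case_id, x$label, c("HCC", "DPHCC", "ICC")[x$label + 1],
              x$cohort_tag, mask_count(x$mask)))
  invisible(x)
}

#' Perturb a mask like a second reader's delineation
#'
#' Moves the mask boundary by a smooth random offset field bounded by
#' `jitter_mm`: the perturbed mask is `{x : sd(x) <= u(x)}` where `sd` is
#' the signed Euclidean distance to the boundary (positive outside) and `u`
#' is a smooth field clamped to `[-jitter_mm, jitter_mm]`.  If a draw
#' empties the mask the amplitude is halved, up to 5 attempts.
#'
#' @param mask a binary [volume].
#' @param jitter_mm perturbation scale (0 returns the mask unchanged).
#' @param seed RNG seed.
#' @return A perturbed binary [volume] on the same grid.
#' @export
perturb_mask <- function(mask, jitter_mm, seed = 1L) {
  stopifnot(is_volume(mask))
  if (mask_count(mask) == 0) stop("mask is empty")
  if (jitter_mm == 0) return(mask)
  M <- (mask$data != 0) * 1
  sp <- mask$spacing_mm
  d <- dim(M)
  # signed distance on a cropped neighbourhood of the mask (positive outside)
  pad <- ceiling((jitter_mm + 2) / min(sp))
  ix <- which(M == 1, arr.ind = TRUE)
  lo <- pmax(apply(ix, 2, min) - pad, 1L)
  hi <- pmin(apply(ix, 2, max) + pad, d)
  Mc <- M[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d_out <- sqrt(edt_squared(Mc == 1, sp))     # distance to mask, for outside
  d_in <- sqrt(edt_squared(Mc == 0, sp))      # distance to background
  # distances between voxel centres overshoot the surface by half a voxel
  h <- min(sp) / 2
  sdist <- ifelse(Mc == 1, -(d_in - h), d_out - h)
  run_seeded(seed, {
    u <- gauss_smooth(array(stats::rnorm(length(Mc)), dim(Mc)), 4 / sp)
    u <- u / stats::sd(u) * 0.6 * jitter_mm   # typical offset ~ jitter
    u <- pmin(pmax(u, -jitter_mm), jitter_mm) # hard bound
    u <- array(u, dim(Mc))
    amp <- 1
    for (attempt in 1:5) {
      newc <- (sdist <= amp * u) * 1
      if (sum(newc) > 0) {
        out <- mask
        out$data <- array(0, d)
        out$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- newc
        return(out)
      }
      amp <- amp / 2
    }
    stop("mask perturbation emptied the mask after 5 damped attempts")
  })
}

#' Dice overlap of two masks
#'
#' @param a,b binary [volume]s on one grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(is_volume(a), is_volume(b))
  ai <- a$data != 0; bi <- b$data != 0
  2 * sum(ai & bi) / (sum(ai) + sum(bi))
}

#' Write a phantom cohort to disk as NIfTI + manifest
#'
#' Writes per-case AP/PP volumes and masks under `dir` and a
#' `manifest.csv` with columns `case_id`, `cohort_tag`, `label` and file
#' paths (the format read back by [ingest_manifest]).
#'
#' @param cases list of case records.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default TRUE).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cases, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  rows <- lapply(cases, function(cc) {
    base <- file.path(dir, cc$case_id)
    paths <- c(ap_path = paste0(base, "_ap", ext),
               pp_path = paste0(base, "_pp", ext),
               mask_path = paste0(base, "_mask", ext))
    write_nifti(cc$ap_volume, paths["ap_path"])
    write_nifti(cc$pp_volume, paths["pp_path"])
    write_nifti(cc$mask, paths["mask_path"])
    data.frame(case_id = cc$case_id, cohort_tag = cc$cohort_tag,
               label = cc$label, t(paths))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
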