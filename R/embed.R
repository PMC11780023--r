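#' Deep-feature backend specification
#'
#' The four named transfer-learning backends carry their penultimate-layer
#' embedding dimensions as contracts: ViT 1024, vgg19 4096, googlenet 1024,
#' inception_v3 2048 (input 224x224 except inception_v3's 299x299).  No deep
#' learning runtime is available offline, so `weights = "pretrained"` raises
#' an explicit error; `weights = "random"` (and the `pseudo` backend) run a
#' deterministic seeded random filterbank producing embeddings of exactly
#' the contracted dimension.
#'
#' @param name one of `"pseudo"`, `"vit"`, `"vgg19"`, `"googlenet"`,
#'   `"inception_v3"`.
#' @param embed_dim embedding length; fixed by `name` for the four named
#'   backends, configurable for `pseudo` (default 256).
#' @param input_size `(H, W)` the crop is resized to before embedding.
#' @param weights `"random"` (seeded filterbank) or `"pretrained"`
#'   (unavailable offline; errors at embedding time).
#' @param seed filterbank seed.
#' @return A list of class `backend_spec`.
#' @export
backend_spec <- function(name = c("pseudo", "vit", "vgg19", "googlenet",
                                  "inception_v3"),
                         embed_dim = NULL, input_size = NULL,
                         weights = c("random", "pretrained"), seed = 0L) {
  name <- match.arg(name)
  weights <- match.arg(weights)
  dims <- c(vit = 1024L, vgg19 = 4096L, googlenet = 1024L,
            inception_v3 = 2048L)
  sizes <- list(vit = c(224L, 224L), vgg19 = c(224L, 224L),
                googlenet = c(224L, 224L), inception_v3 = c(299L, 299L),
                pseudo = c(64L, 64L))
  if (name != "pseudo") {
    if (!is.null(embed_dim) && embed_dim != dims[[name]])
      stop(name, " backend embedding dimension is fixed at ", dims[[name]])
    embed_dim <- dims[[name]]
  } else if (is.null(embed_dim)) {
    embed_dim <- 256L
  }
  if (is.null(input_size)) input_size <- sizes[[name]]
  structure(list(name = name, embed_dim = as.integer(embed_dim),
                 input_size = as.integer(input_size), weights = weights,
                 seed = as.integer(seed)),
            class = "backend_spec")
}

# Cache of filterbank weights keyed by backend identity.
.embed_cache <- new.env(parent = emptyenv())

embed_weights <- function(backend) {
  key <- paste(backend$name, backend$embed_dim, backend$seed, sep = "|")
  w <- .embed_cache[[key]]
  if (is.null(w)) {
    w <- run_seeded(str_seed(backend$name, backend$seed), {
      n_kern <- 24L; ks <- 5L
      kernels <- array(stats::rnorm(ks * ks * n_kern), c(ks * ks, n_kern))
      kernels <- sweep(kernels, 2, colMeans(kernels))   # zero-mean filters
      n_hidden <- n_kern * 16L * 2L                     # avg + max pools
      proj <- matrix(stats::rnorm(n_hidden * backend$embed_dim,
                                  sd = 1 / sqrt(n_hidden)),
                     n_hidden, backend$embed_dim)
      bias <- stats::rnorm(backend$embed_dim, sd = 0.1)
      list(kernels = kernels, proj = proj, bias = bias,
           n_kern = n_kern, ks = ks)
    })
    .embed_cache[[key]] <- w
  }
  w
}

#' Embed one 2-D tumor crop
#'
#' Resizes the crop (bilinear) to the backend input size, min-max
#' standardizes it, and runs the deterministic filterbank: a bank of 24
#' seeded zero-mean 5x5 convolution kernels at a fixed 64x64 working
#' resolution, ReLU, 4x4-grid average and max pooling, then a seeded random
#' projection with tanh nonlinearity to exactly `embed_dim` values.  Output
#' is reproducible given the backend spec and varies with image content.
#'
#' @param image 2-D numeric matrix (one crop from [extract_stack]).
#' @param backend a [backend_spec].
#' @return Numeric vector of length `backend$embed_dim`.
#' @export
embed_slice <- function(image, backend = backend_spec("pseudo")) {
  stopifnot(inherits(backend, "backend_spec"))
  if (!is.matrix(image) || !length(image)) stop("image must be a nonempty matrix")
  if (backend$weights == "pretrained")
    stop("pretrained weights for backend '", backend$name,
         "' are not available in this offline build; use weights = \"random\" ",
         "or the 'pseudo' backend (deterministic seeded filterbank)")
  img <- resize2d(image, backend$input_size)
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  img <- (img - 0.45) / 0.225              # fixed channel normalization
  work <- resize2d(img, c(64L, 64L))
  w <- embed_weights(backend)
  feat <- conv_pool_features(work, w)
  as.numeric(tanh(crossprod(w$proj, feat) + w$bias))
}

# Bilinear resize via the separable interpolation matrices.
resize2d <- function(m, size) {
  W1 <- interp_matrix(nrow(m), 1, size[1], nrow(m) / size[1])
  W2 <- interp_matrix(ncol(m), 1, size[2], ncol(m) / size[2])
  W1 %*% m %*% t(W2)
}

# 24-kernel valid convolution (im2col), ReLU, 4x4 avg+max pooling.
conv_pool_features <- function(img, w) {
  ks <- w$ks
  n <- nrow(img); m <- ncol(img)
  no <- n - ks + 1L; mo <- m - ks + 1L
  # im2col: patches as rows
  cols <- matrix(0, no * mo, ks * ks)
  k <- 1L
  for (dj in 0:(ks - 1)) for (di in 0:(ks - 1)) {
    cols[, k] <- as.vector(img[(1 + di):(no + di), (1 + dj):(mo + dj)])
    k <- k + 1L
  }
  resp <- pmax(cols %*% w$kernels, 0)      # (no*mo) x n_kern, ReLU
  gi <- pmin((seq_len(no) - 1L) %/% ceiling(no / 4), 3L)
  gj <- pmin((seq_len(mo) - 1L) %/% ceiling(mo / 4), 3L)
  cell <- as.vector(outer(gi, gj, function(a, b) a + 4L * b)) + 1L
  avg <- rowsum(resp, cell) / as.vector(table(cell))
  mx <- apply(resp, 2, function(col) tapply(col, cell, max))
  c(as.vector(avg), as.vector(mx))
}

#' Aggregate the five slice embeddings of one case-phase
#'
#' Element-wise mean (or max) over exactly five equal-length vectors;
#' permutation-invariant in the slice order.
#'
#' @param slice_vectors list of 5 numeric vectors.
#' @param method `"mean"` (default) or `"max"`.
#' @return One vector of the common length.
#' @export
aggregate_case <- function(slice_vectors, method = c("mean", "max")) {
  method <- match.arg(method)
  if (length(slice_vectors) != 5L) stop("expected exactly 5 slice vectors")
  len <- unique(vapply(slice_vectors, length, 1L))
  if (length(len) != 1L) stop("slice vectors differ in length")
  M <- do.call(cbind, slice_vectors)
  if (method == "mean") rowMeans(M) else apply(M, 1, max)
}

#' Deep-feature table for a cohort
#'
#' Embeds every crop of every stack and aggregates the five slices per
#' case-phase into one row.  Column names are
#' `"<phase>_<backend>_dtl_<k>"`.
#'
#' @param stacks named list of `slice_stack`s from [cohort_stacks].
#' @param backend a [backend_spec].
#' @param aggregate passed to [aggregate_case].
#' @return data.frame, rows = case ids, one column block per phase.
#' @export
deep_feature_table <- function(stacks, backend = backend_spec("pseudo"),
                               aggregate = "mean") {
  case_ids <- unique(vapply(stacks, function(s) s$case_id, ""))
  phases <- unique(vapply(stacks, function(s) s$phase, ""))
  blocks <- list()
  for (ph in phases) {
    rows <- t(vapply(case_ids, function(cid) {
      st <- stacks[[paste(cid, ph, sep = "_")]]
      if (is.null(st)) stop("missing stack for ", cid, " ", ph)
      vecs <- lapply(st$images, embed_slice, backend = backend)
      aggregate_case(vecs, aggregate)
    }, numeric(backend$embed_dim)))
    colnames(rows) <- sprintf("%s_%s_dtl_%04d", ph, backend$name,
                              seq_len(backend$embed_dim))
    blocks[[ph]] <- rows
  }
  out <- as.data.frame(do.call(cbind, blocks))
  rownames(out) <- case_ids
  out
}
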