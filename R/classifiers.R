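# The four-classifier bank behind train_model().  No SVM/tree package is
# available in the target environment, so the SVM (RBF C-SVM, one-vs-one,
# Platt-scaled pairwise probabilities) solves its dual with quadprog, and
# the decision tree / random forest are a hand-rolled CART (Gini) and its
# bagged ensemble with per-node feature subsampling.  Logistic regression
# is ridge-penalized multinomial glmnet.

#' Train one classifier
#'
#' @param spec list with `classifier` in `{"svm", "lr", "rf", "dt"}`, an
#'   integer `seed`, and optional engine parameters (`svm_C`, `svm_gamma`,
#'   `rf_trees`, `lr_lambda`).
#' @param X numeric matrix of selected, standardized training features.
#' @param y integer labels (0-based) or factor.
#' @return A fitted model of class `dlr_model` exposing per-class
#'   probability scores via [predict_proba].
#' @export
train_model <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  cls <- spec$classifier
  if (is.null(cls)) stop("spec$classifier missing")
  seed <- if (is.null(spec$seed)) 0L else spec$seed
  fit <- switch(cls,
    lr = {
      lam <- if (is.null(spec$lr_lambda)) 0.01 else spec$lr_lambda
      glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                     lambda = c(lam * 10, lam), standardize = FALSE)
    },
    svm = svm_fit_multi(X, y,
                        C = if (is.null(spec$svm_C)) 1 else spec$svm_C,
                        gamma = spec$svm_gamma),
    rf = rf_fit(X, y,
                n_trees = if (is.null(spec$rf_trees)) 500L else spec$rf_trees,
                seed = seed),
    dt = cart_fit(X, as.integer(y) - 1L, nlev = nlevels(y)),
    stop("unknown classifier name: ", cls))
  structure(list(type = cls, fit = fit, levels = levels(y),
                 features = colnames(X), spec = spec),
            class = "dlr_model")
}

#' Per-class probability scores
#'
#' @param model a `dlr_model` from [train_model].
#' @param X feature matrix with the training columns.
#' @return Matrix `n x n_classes` of probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "dlr_model"))
  X <- as.matrix(X)
  if (!is.null(model$features)) X <- X[, model$features, drop = FALSE]
  P <- switch(model$type,
    lr = {
      p <- predict(model$fit, newx = X, type = "response")
      p[, , dim(p)[3]]
    },
    svm = svm_predict_multi(model$fit, X),
    rf = rf_predict(model$fit, X),
    dt = cart_predict(model$fit, X))
  P <- pmax(P, 1e-12)
  P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}

#' @export
print.dlr_model <- function(x, ...) {
  cat(sprintf("<dlr_model> %s, %d feature(s), classes: %s\n", x$type,
              length(x$features), paste(x$levels, collapse = "/")))
  invisible(x)
}

## ---- RBF SVM via the quadprog dual -------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# Binary C-SVM: solve min 1/2 a'Qa - 1'a, y'a = 0, 0 <= a <= C.
svm_fit_binary <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  Dmat <- Q + diag(1e-8, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- a > 1e-8
  f_no_b <- as.vector(K %*% (a * y))
  margin <- a > 1e-6 & a < C - 1e-6
  b <- if (any(margin)) mean(y[margin] - f_no_b[margin]) else
    -(max(f_no_b[y == -1 & sv]) + min(f_no_b[y == 1 & sv])) / 2
  f <- f_no_b + b
  platt <- platt_fit(f, y)
  list(alpha_y = (a * y)[sv], sv = which(sv), b = b, platt = platt)
}

# Platt scaling: sigmoid P(y=1|f) = 1/(1+exp(A f + B)) by Newton iterations
# with the usual smoothed targets.
platt_fit <- function(f, y) {
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  for (it in 1:50) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))                         # p = sigma(-(A f + B))
    g <- c(-sum((t - p) * f), -sum(t - p))        # gradient wrt (A, B)
    w <- p * (1 - p)
    H <- -rbind(c(sum(w * f^2), sum(w * f)),
                c(sum(w * f), sum(w))) - diag(1e-10, 2)
    step <- tryCatch(solve(H, g), error = function(e) c(0, 0))
    A <- A - step[1]; B <- B - step[2]
    if (max(abs(step)) < 1e-10) break
  }
  c(A = A, B = B)
}

svm_fit_multi <- function(X, y, C = 1, gamma = NULL) {
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  lev <- levels(y)
  pairs <- utils::combn(seq_along(lev), 2)
  fits <- lapply(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    idx <- which(y == lev[i] | y == lev[j])
    yy <- ifelse(y[idx] == lev[i], 1, -1)
    Xs <- X[idx, , drop = FALSE]
    K <- rbf_kernel(Xs, Xs, gamma)
    fit <- svm_fit_binary(K, yy, C)
    list(i = i, j = j, Xsv = Xs[fit$sv, , drop = FALSE],
         alpha_y = fit$alpha_y, b = fit$b, platt = fit$platt)
  })
  list(fits = fits, gamma = gamma, n_classes = length(lev))
}

# Pairwise probabilities coupled by averaging: p_i ~ mean_j r_{i|ij}.
svm_predict_multi <- function(model, X) {
  k <- model$n_classes
  P <- matrix(0, nrow(X), k)
  for (fit in model$fits) {
    K <- rbf_kernel(X, fit$Xsv, model$gamma)
    f <- as.vector(K %*% fit$alpha_y) + fit$b
    r <- 1 / (1 + exp(fit$platt["A"] * f + fit$platt["B"]))
    P[, fit$i] <- P[, fit$i] + r
    P[, fit$j] <- P[, fit$j] + (1 - r)
  }
  P / (k - 1)
}

## ---- CART (Gini) and bagged forest -------------------------------------

# Recursive CART with Gini impurity; per-node feature subsampling when
# `mtry` is given (forest mode).  Leaves store class proportions.
cart_fit <- function(X, y0, nlev, max_depth = Inf, min_split = 2L,
                     mtry = NULL) {
  grow <- function(idx, depth) {
    counts <- tabulate(y0[idx] + 1L, nlev)
    probs <- counts / length(idx)
    if (length(idx) < min_split || depth >= max_depth ||
        sum(counts > 0) == 1L)
      return(list(leaf = TRUE, probs = probs))
    feats <- seq_len(ncol(X))
    if (!is.null(mtry) && mtry < length(feats))
      feats <- sample(feats, mtry)
    best <- NULL
    for (fi in feats) {
      xv <- X[idx, fi]
      o <- order(xv)
      xs <- xv[o]; ys <- y0[idx][o] + 1L
      n <- length(ys)
      cum <- matrix(0, n, nlev)
      for (cl in seq_len(nlev)) cum[, cl] <- cumsum(ys == cl)
      valid <- which(xs[-n] < xs[-1])
      if (!length(valid)) next
      nl <- valid
      nr <- n - nl
      gl <- 1 - rowSums((cum[valid, , drop = FALSE] / nl)^2)
      tot <- cum[n, ]
      cr <- sweep(-cum[valid, , drop = FALSE], 2, tot, "+")
      gr <- 1 - rowSums((cr / nr)^2)
      score <- (nl * gl + nr * gr) / n
      m <- which.min(score)
      if (is.null(best) || score[m] < best$score - 1e-12) {
        best <- list(score = score[m], feature = fi,
                     threshold = (xs[valid[m]] + xs[valid[m] + 1]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, probs = probs))
    go_left <- X[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  list(root = grow(seq_len(nrow(X)), 0L), nlev = nlev)
}

cart_predict <- function(model, X) {
  n <- nrow(X)
  P <- matrix(0, n, model$nlev)
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$leaf) {
      P[idx, ] <<- matrix(node$probs, length(idx), model$nlev, byrow = TRUE)
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(model$root, seq_len(n))
  P
}

rf_fit <- function(X, y, n_trees = 500L, seed = 0L) {
  y0 <- as.integer(y) - 1L
  nlev <- nlevels(y)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- run_seeded(seed, {
    lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(nrow(X), replace = TRUE)
      tr <- cart_fit(X[boot, , drop = FALSE], y0[boot], nlev,
                     min_split = 2L, mtry = mtry)
      tr
    })
  })
  list(trees = trees, nlev = nlev)
}

rf_predict <- function(model, X) {
  P <- matrix(0, nrow(X), model$nlev)
  for (tr in model$trees) P <- P + cart_predict(tr, X)
  P / length(model$trees)
}
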