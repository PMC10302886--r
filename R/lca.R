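#' Delta kernel on categorical labels
#'
#' Trial-by-trial label agreement: entry (i, j) is 1 when the labels are
#' equal and 0 otherwise.
#'
#' @param labels category vector (>= 1 entry).
#' @return n x n 0/1 matrix.
#' @export
delta_kernel <- function(labels) {
  if (length(labels) == 0L) stop_param("`labels` must be non-empty.")
  outer(labels, labels, `==`) * 1
}

#' Double-center a kernel matrix
#'
#' Applies the empirical centering matrix on both sides,
#' `Kbar = Itilde K Itilde` with `Itilde = I - 11'/n`; idempotent on
#' already-centered input.
#'
#' @param K square symmetric matrix.
#' @return Centered matrix (row and column sums 0).
#' @export
center_kernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop_param("`K` must be square.")
  n <- nrow(K)
  rm <- rowMeans(K)
  cm <- colMeans(K)
  K - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + mean(K)
}

#' Weighted Gaussian kernel over feature rows
#'
#' `entry(i, j) = exp(-||(x_i - x_j)' W||^2 / 2)`: a Gaussian kernel whose
#' (inverse-covariance) metric `W W'` is the learnable weighting of the
#' supervised alignment step.
#'
#' @param features n x P matrix.
#' @param W P x d weighting matrix.
#' @return n x n kernel matrix with unit diagonal.
#' @export
weighted_gaussian_kernel <- function(features, W) {
  if (!is.matrix(W)) W <- matrix(W, ncol = 1L)
  if (nrow(W) != ncol(features)) {
    stop_param("W has %d rows but features have %d columns.",
               nrow(W), ncol(features))
  }
  Z <- features %*% W
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Z)
  D2[D2 < 0] <- 0
  K <- exp(-D2 / 2)
  diag(K) <- 1
  K
}

#' Centered kernel alignment
#'
#' Normalized Frobenius inner product of two centered kernel matrices,
#' `<Ka, Kb>_F / (||Ka||_F ||Kb||_F)`; in \[0, 1\] for PSD inputs, 1 iff the
#' kernels are positive multiples of each other, and 0 (with a warning)
#' when either norm vanishes.
#'
#' @param Ka,Kb centered kernel matrices of equal size.
#' @param center double-center the inputs first (default TRUE; set FALSE
#'   if they are already centered).
#' @return Alignment value.
#' @export
cka_alignment <- function(Ka, Kb, center = TRUE) {
  if (!all(dim(Ka) == dim(Kb))) stop_param("Kernel size mismatch.")
  if (center) {
    Ka <- center_kernel(Ka)
    Kb <- center_kernel(Kb)
  }
  na <- sqrt(sum(Ka^2))
  nb <- sqrt(sum(Kb^2))
  if (na == 0 || nb == 0) {
    warn("Zero-norm centered kernel; alignment undefined, returning 0.")
    return(0)
  }
  sum(Ka * Kb) / (na * nb)
}

#' Supervised CKA feature weighting
#'
#' Learns the P x d weighting matrix W maximizing the centered kernel
#' alignment between the W-parameterized Gaussian kernel on the features
#' and the delta kernel on the labels, by full-batch gradient ascent with
#' an adaptive step (accepted steps grow it, rejected steps shrink it).
#' Features are standardized column-wise first; W is initialized from the
#' top-d principal axes (scaled so the kernel starts at a usable length
#' scale), making the fit deterministic for a given input.
#'
#' @param features n x P matrix.
#' @param labels per-row categories (>= 2 distinct).
#' @param d weighting rank, default `min(P, 32)`.
#' @param max_iter maximum ascent iterations (500).
#' @param tol stop when the relative alignment change over `patience`
#'   iterations falls below this (1e-6).
#' @param patience window for the stopping rule (10).
#' @param step0 initial step size.
#' @param seed integer seed (reserved for stochastic variants; the default
#'   initialization is deterministic).
#' @return A `cka_fit`: list with `W` (P x d), `alignment` (final),
#'   `alignment_trace` (per accepted iteration), standardization
#'   `center`/`scale`, and the inputs' dimensions.
#' @export
fit_cka <- function(features, labels, d = NULL, max_iter = 500L,
                    tol = 1e-6, patience = 10L, step0 = 1, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features); P <- ncol(features)
  if (length(labels) != n) stop_param("labels/rows mismatch.")
  if (length(unique(labels)) < 2L) {
    stop_param("Need >= 2 distinct labels; the alignment target is degenerate.")
  }
  d <- as.integer(d %||% min(P, 32L))
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(features, 2L, ctr), 2L, scl, `/`)
  Lbar <- center_kernel(delta_kernel(labels))
  Lnorm <- sqrt(sum(Lbar^2))

  # Supervised init: leading directions of the centered class-mean matrix
  # (the label-discriminative subspace), padded with principal axes when
  # d exceeds the class count; scaled so the median projected pairwise
  # squared distance is ~2 (a usable kernel length scale).
  cls <- unique(labels)
  M <- do.call(rbind, lapply(cls, function(g) colMeans(Xs[labels == g, , drop = FALSE])))
  M <- scale(M, scale = FALSE)
  svm <- svd(M, nu = 0L)
  keep <- which(svm$d > max(svm$d) * 1e-8)
  Wm <- svm$v[, head(keep, d), drop = FALSE]
  if (ncol(Wm) < d) {
    sv <- svd(scale(Xs, scale = FALSE), nu = 0L, nv = min(P, d))
    extra <- sv$v[, seq_len(min(ncol(sv$v), d - ncol(Wm))), drop = FALSE]
    # orthogonalize the padding against the supervised block
    extra <- extra - Wm %*% crossprod(Wm, extra)
    W <- cbind(Wm, extra)
  } else {
    W <- Wm
  }
  if (ncol(W) < d) W <- cbind(W, matrix(0, P, d - ncol(W)))
  Z <- Xs %*% W
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Z)
  md <- median(D2[upper.tri(D2)])
  if (md > 0) W <- W * sqrt(2 / md)

  align_of <- function(W) {
    K <- weighted_gaussian_kernel(Xs, W)
    Kbar <- center_kernel(K)
    kn <- sqrt(sum(Kbar^2))
    a <- if (kn == 0) 0 else sum(Kbar * Lbar) / (kn * Lnorm)
    list(a = a, K = K, Kbar = Kbar, kn = kn)
  }

  cur <- align_of(W)
  trace <- cur$a
  step <- step0
  for (it in seq_len(max_iter)) {
    # d alignment / d K, then chain through the Gaussian kernel
    C <- if (cur$kn == 0) Lbar / Lnorm else {
      Lbar / (cur$kn * Lnorm) - cur$a * cur$Kbar / cur$kn^2
    }
    C <- center_kernel(C)          # d Kbar / d K wraps both sides in Itilde
    B <- C * cur$K
    G <- -2 * crossprod(Xs, (diag(rowSums(B)) - B) %*% Xs) %*% W
    gn <- sqrt(sum(G^2))
    if (gn < 1e-14) break
    accepted <- FALSE
    for (try in 1:20) {
      Wnew <- W + step * G / gn
      nxt <- align_of(Wnew)
      if (nxt$a > cur$a) {
        W <- Wnew; cur <- nxt
        step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cur$a)
    if (!accepted) break
    nb <- length(trace)
    if (nb > patience) {
      prev <- trace[nb - patience]
      if (abs(cur$a - prev) < tol * max(abs(prev), 1e-12)) break
    }
  }
  structure(list(W = W, alignment = cur$a, alignment_trace = trace,
                 center = ctr, scale = scl, n = n, P = P, d = d,
                 seed = as.integer(seed)),
            class = "cka_fit")
}

#' @export
print.cka_fit <- function(x, ...) {
  cat(sprintf("<cka_fit> P=%d, d=%d, n=%d: alignment %.4f after %d accepted steps\n",
              x$P, x$d, x$n, x$alignment, length(x$alignment_trace) - 1L))
  invisible(x)
}

#' Project features through a fitted CKA weighting
#'
#' Applies the training standardization and the learned soft weighting
#' `Xtilde = X W`.
#'
#' @param fit a `cka_fit`.
#' @param features n x P matrix on the same columns as the training data.
#' @return n x d projected matrix.
#' @export
project_cka <- function(fit, features) {
  stopifnot(inherits(fit, "cka_fit"))
  features <- as.matrix(features)
  Xs <- sweep(sweep(features, 2L, fit$center), 2L, fit$scale, `/`)
  Xs %*% fit$W
}

#' Per-feature relevance from a CKA weighting
#'
#' Relevance of feature p is the l2 norm of row p of W, normalized to sum
#' to 1; an all-zero W yields a uniform map with a warning.
#'
#' @param fit a `cka_fit` (or a bare W matrix).
#' @return Nonnegative numeric vector summing to 1.
#' @export
feature_relevance <- function(fit) {
  W <- if (inherits(fit, "cka_fit")) fit$W else as.matrix(fit)
  r <- sqrt(rowSums(W^2))
  if (sum(r) == 0) {
    warn("Zero weighting matrix; returning a uniform relevance map.")
    return(rep(1 / length(r), length(r)))
  }
  r / sum(r)
}

#' Electrode relevance by back-projection
#'
#' Aggregates per-feature relevance onto electrodes: an electrode's score
#' is the mean relevance over all connectivity features whose channel pair
#' includes it (across windows, bands and measures), normalized so the
#' maximum is 1.
#'
#' @param per_feature relevance vector (from [feature_relevance()]).
#' @param feature_index tibble with columns `ch1`, `ch2` mapping features
#'   to channel pairs (the `index` of an `fc_features` object).
#' @param montage channel names; defaults to those present in the index.
#' @return Tibble with columns `electrode`, `relevance` sorted by
#'   decreasing relevance.
#' @export
electrode_relevance <- function(per_feature, feature_index, montage = NULL) {
  if (is.null(feature_index) || !all(c("ch1", "ch2") %in% names(feature_index))) {
    stop_param("`feature_index` must map features to channel pairs (ch1, ch2).")
  }
  if (nrow(feature_index) != length(per_feature)) {
    stop_param("feature_index rows (%d) != relevance length (%d).",
               nrow(feature_index), length(per_feature))
  }
  montage <- montage %||% unique(c(feature_index$ch1, feature_index$ch2))
  score <- vapply(montage, function(e) {
    hit <- feature_index$ch1 == e | feature_index$ch2 == e
    if (!any(hit)) 0 else mean(per_feature[hit])
  }, numeric(1))
  if (max(score) > 0) score <- score / max(score)
  tibble::tibble(electrode = montage, relevance = as.numeric(score)) |>
    dplyr::arrange(dplyr::desc(relevance))
}

#' First canonical correlation pair
#'
#' Whitens both (standardized) blocks with a ridge term added to each
#' auto-covariance, takes the SVD of the whitened cross-covariance, and
#' returns the first canonical pair under unit-variance constraints — the
#' single-dimensionality latent subspace of the alignment.  The first
#' nonzero entry of `alpha_x` is forced positive for reproducibility.
#'
#' @param X n x P matrix; @param Y n x Q matrix.
#' @param regularization ridge coefficient, scaled by the mean diagonal of
#'   each auto-covariance (default 1e-3; 0 for exact CCA on full-rank
#'   input).
#' @param standardize z-score columns first (TRUE).
#' @return A `cca_fit`: list with `alpha_x`, `alpha_y`, `r`, `r_squared`,
#'   and the standardization used.
#' @export
fit_cca <- function(X, Y, regularization = 1e-3, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop_param("X and Y must have the same number of rows.")
  if (n <= 2L) stop_param("Need n > 2 trials.")
  cx <- colMeans(X); cy <- colMeans(Y)
  sx <- apply(X, 2L, sd); sy <- apply(Y, 2L, sd)
  sx[sx < 1e-12] <- 1; sy[sy < 1e-12] <- 1
  if (standardize) {
    X <- sweep(sweep(X, 2L, cx), 2L, sx, `/`)
    Y <- sweep(sweep(Y, 2L, cy), 2L, sy, `/`)
  } else {
    X <- sweep(X, 2L, cx); Y <- sweep(Y, 2L, cy)
    sx[] <- 1; sy[] <- 1
  }
  Sxx <- crossprod(X) / (n - 1)
  Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  if (regularization > 0) {
    Sxx <- Sxx + regularization * mean(diag(Sxx)) * diag(ncol(X))
    Syy <- Syy + regularization * mean(diag(Syy)) * diag(ncol(Y))
  }
  strict <- regularization == 0
  Wx <- inv_sqrt(Sxx, "X", strict = strict)
  Wy <- inv_sqrt(Syy, "Y", strict = strict)
  M <- Wx %*% Sxy %*% Wy
  sv <- svd(M, nu = 1L, nv = 1L)
  r <- min(max(sv$d[1L], 0), 1)
  ax <- as.numeric(Wx %*% sv$u[, 1L])
  ay <- as.numeric(Wy %*% sv$v[, 1L])
  nz <- which(abs(ax) > 1e-12)[1L]
  if (!is.na(nz) && ax[nz] < 0) { ax <- -ax; ay <- -ay }
  structure(list(alpha_x = ax, alpha_y = ay, r = r, r_squared = r^2,
                 center_x = cx, center_y = cy, scale_x = sx, scale_y = sy,
                 regularization = regularization, n = n),
            class = "cca_fit")
}

inv_sqrt <- function(S, side, strict = FALSE) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  if (!any(pos)) {
    stop_param("Auto-covariance of %s is numerically zero; add regularization.",
               side)
  }
  if (strict && !all(pos)) {
    stop_param(paste0("Rank-deficient auto-covariance on the %s side with ",
                      "regularization 0; set `regularization` > 0 (e.g. the ",
                      "default 1e-3) or remove collinear columns."), side)
  }
  v <- e$vectors[, pos, drop = FALSE]
  v %*% diag(1 / sqrt(e$values[pos]), sum(pos)) %*% t(v)
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> n=%d: r = %.4f (r^2 = %.4f)\n", x$n, x$r, x$r_squared))
  invisible(x)
}

#' Canonical variates for new data
#'
#' @param fit a `cca_fit`.
#' @param X,Y feature blocks on the training columns.
#' @return Tibble with per-trial canonical variates `u` and `v`.
#' @export
cca_variates <- function(fit, X, Y) {
  stopifnot(inherits(fit, "cca_fit"))
  X <- sweep(sweep(as.matrix(X), 2L, fit$center_x), 2L, fit$scale_x, `/`)
  Y <- sweep(sweep(as.matrix(Y), 2L, fit$center_y), 2L, fit$scale_y, `/`)
  tibble::tibble(u = as.numeric(X %*% fit$alpha_x),
                 v = as.numeric(Y %*% fit$alpha_y))
}

#' Two-step Labeled Correlation Alignment
#'
#' Step 1 fits the supervised CKA weighting of each modality against the
#' label kernel independently; step 2 runs CCA on the projected blocks
#' `Xtilde = X W_X`, `Ytilde = Y W_Y`.  `two_step = FALSE` gives the
#' single-step baseline (CCA on the raw blocks, no label information).
#' Relevance maps are emitted from the EEG-side weighting; when `X` is an
#' `fc_features` object the electrode back-projection is included.
#'
#' @param X EEG feature block: matrix or `fc_features`.
#' @param Y audio feature block: matrix or `audio_features`.
#' @param labels per-trial labels (taken from `X` when absent).
#' @param d CKA rank for both sides (default `min(P, 32)` per side).
#' @param regularization CCA ridge (1e-3).
#' @param two_step fit the CKA step (TRUE); FALSE is the CCA-only
#'   baseline.
#' @param max_iter,seed passed to [fit_cka()].
#' @return An `lca_fit`: list with `cka_x`, `cka_y` (NULL when
#'   single-step), `cca`, `r`, `r_squared`, `relevance` (per-feature),
#'   `electrode_relevance` (tibble or NULL), `variates` (per-trial u, v
#'   with labels), and `labels`.
#' @export
lca <- function(X, Y, labels = NULL, d = NULL, regularization = 1e-3,
                two_step = TRUE, max_iter = 200L, seed = 1L) {
  xin <- X; yin <- Y
  fidx <- NULL
  if (inherits(X, "fc_features")) {
    labels <- labels %||% X$labels
    fidx <- X$index
    X <- X$values
  }
  if (inherits(Y, "audio_features")) Y <- Y$values
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_param("Trial counts differ between modalities.")
  if (two_step) {
    if (is.null(labels)) stop_param("Labels are required for the two-step fit.")
    if (length(labels) != nrow(X)) stop_param("labels/trials mismatch.")
    cka_x <- fit_cka(X, labels, d = d, max_iter = max_iter, seed = seed)
    cka_y <- fit_cka(Y, labels, d = d, max_iter = max_iter, seed = seed)
    Xt <- project_cka(cka_x, X)
    Yt <- project_cka(cka_y, Y)
  } else {
    cka_x <- cka_y <- NULL
    Xt <- X; Yt <- Y
  }
  cca <- fit_cca(Xt, Yt, regularization = regularization)
  rel <- if (two_step) feature_relevance(cka_x) else
    rep(1 / ncol(X), ncol(X))
  erel <- if (!is.null(fidx)) electrode_relevance(rel, fidx) else NULL
  vts <- cca_variates(cca, Xt, Yt)
  if (!is.null(labels)) vts$label <- labels
  structure(list(cka_x = cka_x, cka_y = cka_y, cca = cca,
                 r = cca$r, r_squared = cca$r_squared,
                 relevance = rel, electrode_relevance = erel,
                 variates = vts, labels = labels, two_step = two_step,
                 feature_index = fidx),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> %s: r = %.4f, r^2 = %.4f\n",
              if (x$two_step) "two-step (CKA + CCA)" else "single-step (CCA only)",
              x$r, x$r_squared))
  if (x$two_step) {
    cat(sprintf("  CKA alignment: X %.4f, Y %.4f\n",
                x$cka_x$alignment, x$cka_y$alignment))
  }
  invisible(x)
}

#' @export
tidy.lca_fit <- function(x, ...) {
  out <- tibble::tibble(feature = seq_along(x$relevance),
                        relevance = x$relevance)
  if (!is.null(x$feature_index)) {
    out <- dplyr::bind_cols(out, x$feature_index[, setdiff(names(x$feature_index), "feature")])
  }
  out
}

#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, r_squared = x$r_squared,
    alignment_x = if (x$two_step) x$cka_x$alignment else NA_real_,
    alignment_y = if (x$two_step) x$cka_y$alignment else NA_real_,
    two_step = x$two_step, n = x$cca$n
  )
}

#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(
    side = rep(c("x", "y"), c(length(x$alpha_x), length(x$alpha_y))),
    term = c(seq_along(x$alpha_x), seq_along(x$alpha_y)),
    coefficient = c(x$alpha_x, x$alpha_y)
  )
}

#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, n = x$n,
                 regularization = x$regularization)
}

#' @export
tidy.cka_fit <- function(x, ...) {
  tibble::tibble(feature = seq_len(x$P), relevance = feature_relevance(x))
}

#' @export
glance.cka_fit <- function(x, ...) {
  tibble::tibble(alignment = x$alignment, n = x$n, P = x$P, d = x$d,
                 iterations = length(x$alignment_trace) - 1L)
}
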