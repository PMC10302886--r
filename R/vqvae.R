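#' VQ-VAE configuration
#'
#' Architecture and training settings for the envelope autoencoder: a
#' segment-wise (stride = kernel) 1-D encoder/decoder — each length-
#' `seg_len` slice of the envelope is encoded through a tanh hidden layer
#' to a D-dimensional latent, snapped to one of K codebook vectors, and
#' decoded back through a mirrored layer with a softplus head (envelopes
#' are nonnegative).
#'
#' @param seg_len samples per encoded segment (8).
#' @param hidden hidden-layer width (32).
#' @param K codebook size (64).
#' @param D latent dimension (16).
#' @param beta commitment weight in \[0, 1\] (0.25).
#' @param learning_rate Adam step size (0.02).
#' @param epochs full-batch training epochs (300).
#' @param seed integer seed controlling initialization.
#' @return A `vqvae_config` list.
#' @export
vqvae_config <- function(seg_len = 8L, hidden = 32L, K = 64L, D = 16L,
                         beta = 0.25, learning_rate = 0.02, epochs = 300L,
                         seed = 1L) {
  check_scalar_number(beta, "beta", 0, 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  if (K < 2L) stop_param("Codebook needs K >= 2 entries.")
  structure(list(seg_len = as.integer(seg_len), hidden = as.integer(hidden),
                 K = as.integer(K), D = as.integer(D), beta = beta,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "vqvae_config")
}

#' Nearest-codebook quantization
#'
#' Replaces each latent row by its nearest codebook entry (Euclidean);
#' ties break to the lowest index.  Idempotent: quantizing an already
#' quantized sequence changes nothing.
#'
#' @param h latent vectors: n x D matrix (or a single D-vector).
#' @param codebook K x D matrix of codebook entries.
#' @return List with integer `indices` (length n) and `quantized`
#'   (n x D matrix).
#' @export
quantize <- function(h, codebook) {
  if (is.vector(h)) h <- matrix(h, nrow = 1L)
  if (ncol(h) != ncol(codebook)) {
    stop_param("Latent dimension (%d) != codebook dimension (%d).",
               ncol(h), ncol(codebook))
  }
  hs <- rowSums(h^2)
  cs <- rowSums(codebook^2)
  D2 <- outer(hs, cs, `+`) - 2 * h %*% t(codebook)
  idx <- apply(round(D2, 12L), 1L, which.min)
  list(indices = as.integer(idx),
       quantized = codebook[idx, , drop = FALSE])
}

#' VQ-VAE loss terms
#'
#' Reconstruction, codebook and commitment terms of the vector-quantized
#' training objective: `total = mse(input, reconstruction) +
#' mse(sg(latents), quantized) + beta * mse(latents, sg(quantized))`,
#' where sg is the stop-gradient operation.  Numerically the two latent
#' terms share the same squared error; the stop-gradients only differ in
#' which parameters each term trains (codebook term never reaches the
#' encoder, commitment term never reaches the codebook), which is how the
#' training loop applies them.
#'
#' @param input,reconstruction matching numeric arrays.
#' @param latents,quantized matching numeric arrays.
#' @param beta commitment weight.
#' @return List with `total`, `recon_term`, `codebook_term`,
#'   `commit_term` (the reported commit term includes the beta factor).
#' @export
vqvae_loss <- function(input, reconstruction, latents, quantized, beta) {
  if (length(input) != length(reconstruction)) {
    stop_param("input/reconstruction shape mismatch.")
  }
  if (length(latents) != length(quantized)) {
    stop_param("latents/quantized shape mismatch.")
  }
  recon <- mean((as.numeric(input) - as.numeric(reconstruction))^2)
  lat_mse <- mean((as.numeric(latents) - as.numeric(quantized))^2)
  codebook_term <- lat_mse
  commit_term <- beta * lat_mse
  list(total = recon + codebook_term + commit_term,
       recon_term = recon, codebook_term = codebook_term,
       commit_term = commit_term)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

vqvae_init <- function(config, L) {
  if (L %% config$seg_len != 0L) {
    stop_param("Envelope length (%d) must be a multiple of seg_len (%d).",
               L, config$seg_len)
  }
  withr::with_seed(config$seed, {
    g <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    list(W1 = g(config$hidden, config$seg_len), b1 = numeric(config$hidden),
         W2 = g(config$D, config$hidden), b2 = numeric(config$D),
         E = matrix(rnorm(config$K * config$D, sd = 0.5), config$K, config$D),
         W3 = g(config$hidden, config$D), b3 = numeric(config$hidden),
         W4 = g(config$seg_len, config$hidden), b4 = numeric(config$seg_len))
  })
}

vqvae_encode_segments <- function(params, Xseg) {
  A1 <- tanh(Xseg %*% t(params$W1) + rep(params$b1, each = nrow(Xseg)))
  H <- A1 %*% t(params$W2) + rep(params$b2, each = nrow(Xseg))
  list(A1 = A1, H = H)
}

vqvae_decode_segments <- function(params, Q) {
  A2 <- tanh(Q %*% t(params$W3) + rep(params$b3, each = nrow(Q)))
  Ypre <- A2 %*% t(params$W4) + rep(params$b4, each = nrow(Q))
  list(A2 = A2, Ypre = Ypre, Y = softplus(Ypre))
}

# rows of the (n x L) envelope matrix cut into (n*S x seg_len) segments,
# segment-major within each envelope
to_segments <- function(X, seg_len) {
  n <- nrow(X); S <- ncol(X) / seg_len
  out <- matrix(0, n * S, seg_len)
  for (i in seq_len(n)) {
    for (s in seq_len(S)) {
      out[(i - 1L) * S + s, ] <- X[i, ((s - 1L) * seg_len + 1L):(s * seg_len)]
    }
  }
  out
}

from_segments <- function(seg, n, L) {
  S <- nrow(seg) / n
  out <- matrix(0, n, L)
  for (i in seq_len(n)) {
    out[i, ] <- as.numeric(t(seg[((i - 1L) * S + 1L):(i * S), , drop = FALSE]))
  }
  out
}

#' Train the envelope VQ-VAE
#'
#' Full-batch manual-gradient training of the segment-wise autoencoder
#' with the three-term vector-quantized objective: the reconstruction
#' gradient reaches the decoder and (through the straight-through
#' estimator) the encoder; the codebook term moves only the codebook
#' entries toward their assigned latents; the commitment term (weight
#' beta) moves only the encoder toward the codebook.  Adam updates; dead
#' codebook entries are re-seeded each epoch from the worst-quantized
#' latents.  Deterministic for a fixed config seed.
#'
#' @param envelopes n x L matrix of envelopes (rows), or a list of
#'   equal-length `acoustic_envelope` vectors; n >= 8.
#' @param config a [vqvae_config()].
#' @return A `vqvae_model`: list with `params` (including codebook `E`),
#'   `config`, `loss_history` (per-epoch total), `loss_terms` (final),
#'   and `L`.
#' @export
train_vqvae <- function(envelopes, config = vqvae_config()) {
  if (is.list(envelopes)) envelopes <- do.call(rbind, lapply(envelopes, as.numeric))
  X <- as.matrix(envelopes)
  if (nrow(X) < 8L) stop_param("Need >= 8 envelopes to train.")
  L <- ncol(X)
  params <- vqvae_init(config, L)
  seg_len <- config$seg_len
  Xseg <- to_segments(X, seg_len)
  nseg <- nrow(Xseg)

  adam <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  t_step <- 0
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    enc <- vqvae_encode_segments(params, Xseg)
    qz <- quantize(enc$H, params$E)
    dec <- vqvae_decode_segments(params, qz$quantized)

    recon <- mean((dec$Y - Xseg)^2)
    lat_mse <- mean((enc$H - qz$quantized)^2)
    loss_hist[ep] <- recon + lat_mse + config$beta * lat_mse
    if (!is.finite(loss_hist[ep])) {
      abort(sprintf(paste0("VQ-VAE training diverged at epoch %d ",
                           "(loss not finite); lower the learning rate."), ep),
            class = "lcasonify_divergence_error")
    }

    # backward pass
    dY <- 2 * (dec$Y - Xseg) / length(Xseg)
    dYpre <- dY * sigmoid(dec$Ypre)
    gW4 <- crossprod(dYpre, dec$A2)
    gb4 <- colSums(dYpre)
    dA2 <- dYpre %*% params$W4
    dA2pre <- dA2 * (1 - dec$A2^2)
    gW3 <- crossprod(dA2pre, qz$quantized)
    gb3 <- colSums(dA2pre)
    dQ <- dA2pre %*% params$W3

    # codebook gradient: pull each used entry toward its assigned latents
    gE <- params$E * 0
    dE_rows <- 2 * (qz$quantized - enc$H) / length(enc$H)
    for (k in unique(qz$indices)) {
      rows <- qz$indices == k
      gE[k, ] <- colSums(dE_rows[rows, , drop = FALSE])
    }

    # straight-through to the encoder + commitment
    dH <- dQ + config$beta * 2 * (enc$H - qz$quantized) / length(enc$H)
    gW2 <- crossprod(dH, enc$A1)
    gb2 <- colSums(dH)
    dA1 <- dH %*% params$W2
    dA1pre <- dA1 * (1 - enc$A1^2)
    gW1 <- crossprod(dA1pre, Xseg)
    gb1 <- colSums(dA1pre)

    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, E = gE,
                  W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
    t_step <- t_step + 1
    for (nm in names(params)) {
      adam[[nm]]$m <- b1m * adam[[nm]]$m + (1 - b1m) * grads[[nm]]
      adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1m^t_step)
      vhat <- adam[[nm]]$v / (1 - b2m^t_step)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }

    # re-seed dead codebook entries from the worst-quantized latents
    used <- unique(qz$indices)
    dead <- setdiff(seq_len(config$K), used)
    if (length(dead) > 0L) {
      err <- rowSums((enc$H - qz$quantized)^2)
      worst <- order(err, decreasing = TRUE)[seq_len(min(length(dead), nseg))]
      params$E[dead[seq_along(worst)], ] <- enc$H[worst, , drop = FALSE]
    }
  }

  enc <- vqvae_encode_segments(params, Xseg)
  qz <- quantize(enc$H, params$E)
  dec <- vqvae_decode_segments(params, qz$quantized)
  final <- vqvae_loss(Xseg, dec$Y, enc$H, qz$quantized, config$beta)
  structure(list(params = params, config = config, L = L,
                 loss_history = loss_hist, loss_terms = final,
                 input_stats = list(mean = mean(X), sd = sd(X))),
            class = "vqvae_model")
}

#' @export
print.vqvae_model <- function(x, ...) {
  cat(sprintf("<vqvae_model> L=%d, seg_len=%d, K=%d, D=%d: final loss %.5f (recon %.5f)\n",
              x$L, x$config$seg_len, x$config$K, x$config$D,
              x$loss_terms$total, x$loss_terms$recon_term))
  invisible(x)
}

#' @export
glance.vqvae_model <- function(x, ...) {
  tibble::tibble(loss = x$loss_terms$total,
                 recon = x$loss_terms$recon_term,
                 codebook = x$loss_terms$codebook_term,
                 commit = x$loss_terms$commit_term,
                 epochs = x$config$epochs, K = x$config$K, D = x$config$D)
}

#' Reconstruct envelopes through the trained model
#'
#' @param model a `vqvae_model`.
#' @param X n x L matrix of input sequences.
#' @return n x L matrix of decoded (nonnegative) sequences; attribute
#'   `"codes"` holds the per-segment codebook indices.
#' @export
vqvae_reconstruct <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$L) stop_param("Input length %d != model length %d.",
                                     ncol(X), model$L)
  Xseg <- to_segments(X, model$config$seg_len)
  enc <- vqvae_encode_segments(model$params, Xseg)
  qz <- quantize(enc$H, model$params$E)
  dec <- vqvae_decode_segments(model$params, qz$quantized)
  out <- from_segments(dec$Y, nrow(X), model$L)
  attr(out, "codes") <- matrix(qz$indices, nrow(X), byrow = TRUE)
  out
}

#' EEG-to-envelope front projection
#'
#' Convolution-style linear map with a softplus nonlinearity reducing one
#' trial's FC feature vector to an envelope-length input for the encoder.
#' Each output sample has a localized (Gaussian-bump) receptive field over
#' the feature index, with small seeded weight jitter; the map is fixed at
#' construction, so identical features give identical projections and a
#' zero input yields the bias-determined output.
#'
#' @param n_features feature dimension P of one trial.
#' @param out_len output length (the model envelope length L).
#' @param seed integer seed for the weight jitter.
#' @param gain,bias scale and offset applied before the softplus.
#' @param width receptive-field width in feature-index units (default
#'   `max(0.6, n_features / 24)`; narrower fields preserve more
#'   feature-level detail in the output sequence).
#' @return A `front_projection` closure-free list with the weight matrix
#'   `W` (out_len x P) and `bias`.
#' @export
eeg_front_projection <- function(n_features, out_len, seed = 1L,
                                 gain = 1, bias = 0.5, width = NULL) {
  centers <- seq(0.5, n_features - 0.5, length.out = out_len)
  width <- width %||% max(0.6, n_features / 24)
  W <- outer(seq_len(out_len), seq_len(n_features), function(t, p) {
    exp(-0.5 * ((centers[t] - (p - 0.5)) / width)^2)
  })
  W <- W / rowSums(W)
  W <- withr::with_seed(as.integer(seed), {
    W * (1 + 0.05 * matrix(rnorm(length(W)), nrow(W)))
  })
  structure(list(W = W, bias = bias, gain = gain, n_features = n_features,
                 out_len = out_len, seed = as.integer(seed)),
            class = "front_projection")
}

#' Apply a front projection to feature rows
#'
#' @param front a [eeg_front_projection()].
#' @param features n x P matrix (or a single P-vector).
#' @return n x out_len matrix of nonnegative encoder inputs.
#' @export
front_project <- function(front, features) {
  stopifnot(inherits(front, "front_projection"))
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != front$n_features) {
    stop_param("Feature dimension %d != projection input size %d.",
               ncol(features), front$n_features)
  }
  softplus(front$gain * features %*% t(front$W) + front$bias)
}

#' Spectral transfer-compatibility check
#'
#' The coding model trained on one signal set can only be reused on
#' another if both have similar spectral content and matching array
#' dimensions.  Passes iff the mean 95%-energy spectral bandwidths agree
#' within `tol` (relative to the larger) AND the per-row lengths match.
#'
#' @param source,target matrices of row sequences (the training set and
#'   the candidate encoder input).
#' @param tol allowed relative bandwidth mismatch (0.2).
#' @param fs sampling rate of the sequences (64 Hz envelopes).
#' @return A `transfer_report` list: `pass`, `bandwidth_ok`, `dims_ok`,
#'   `bw_source`, `bw_target`, `tol`.
#' @export
check_transfer_conditions <- function(source, target, tol = 0.2, fs = 64) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0L || nrow(target) == 0L) {
    stop_param("Both feature sets must be non-empty.")
  }
  bw <- function(M) {
    mean(apply(M, 1L, function(x) {
      x <- x - mean(x)
      if (all(x == 0)) return(0)
      p <- Mod(fft(x))[seq_len(floor(length(x) / 2) + 1L)]^2
      freqs <- (seq_along(p) - 1L) * fs / length(x)
      freqs[which(cumsum(p) / sum(p) >= 0.95)[1L]]
    }))
  }
  bw_s <- bw(source); bw_t <- bw(target)
  dims_ok <- ncol(source) == ncol(target)
  bandwidth_ok <- {
    mx <- max(bw_s, bw_t)
    if (mx == 0) TRUE else abs(bw_s - bw_t) / mx <= tol
  }
  structure(list(pass = dims_ok && bandwidth_ok, bandwidth_ok = bandwidth_ok,
                 dims_ok = dims_ok, bw_source = bw_s, bw_target = bw_t,
                 tol = tol),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("<transfer_report> %s: bandwidth %s (%.2f vs %.2f Hz, tol %.2f), dimensions %s\n",
              if (x$pass) "PASS" else "FAIL",
              if (x$bandwidth_ok) "ok" else "mismatch",
              x$bw_source, x$bw_target, x$tol,
              if (x$dims_ok) "ok" else "mismatch"))
  invisible(x)
}

#' Sonify EEG-selected features into acoustic envelopes
#'
#' Feeds front-projected EEG feature rows to the trained envelope
#' autoencoder.  With `smoothing = TRUE` (and a fitted two-step alignment
#' supplied) each trial's features are first replaced by their rank-1
#' reconstruction along the canonical EEG direction — the
#' alignment-selected representation — which removes off-direction noise
#' and yields visibly smoother decoded envelopes than feeding the raw
#' feature rows.  The spectral transfer check against the training
#' envelopes is enforced before decoding.
#'
#' @param model a trained `vqvae_model`.
#' @param features n x P EEG feature matrix (raw scale).
#' @param front a matching [eeg_front_projection()] with
#'   `out_len = model$L`.
#' @param lca_fit an `lca_fit` (required when `smoothing = TRUE`).
#' @param smoothing use the alignment-projected features (TRUE).
#' @param train_envelopes envelopes the model was trained on, for the
#'   transfer check; `NULL` skips the check.
#' @param tol transfer-check bandwidth tolerance.
#' @return n x L matrix of generated envelopes (class keeps the codes
#'   attribute from [vqvae_reconstruct()]).
#' @export
sonify <- function(model, features, front, lca_fit = NULL, smoothing = TRUE,
                   train_envelopes = NULL, tol = 0.5) {
  features <- as.matrix(features)
  if (smoothing) {
    if (is.null(lca_fit) || !inherits(lca_fit, "lca_fit") || !lca_fit$two_step) {
      stop_param("`smoothing = TRUE` needs a fitted two-step `lca_fit`.")
    }
    Xs <- sweep(sweep(features, 2L, lca_fit$cka_x$center), 2L,
                lca_fit$cka_x$scale, `/`)
    beta_dir <- as.numeric(lca_fit$cka_x$W %*% lca_fit$cca$alpha_x)
    nb <- sqrt(sum(beta_dir^2))
    if (nb == 0) stop_param("Degenerate canonical direction.")
    beta_unit <- beta_dir / nb
    u <- as.numeric(Xs %*% beta_unit)
    proj <- outer(u, beta_unit)
    proj <- sweep(sweep(proj, 2L, lca_fit$cka_x$scale, `*`), 2L,
                  lca_fit$cka_x$center, `+`)
    features <- proj
  }
  inputs <- front_project(front, features)
  # calibrate encoder inputs to the scale of the model's training data
  # (the VQ-VAE demands input representations matching its training range)
  if (!is.null(model$input_stats) && sd(inputs) > 0) {
    inputs <- (inputs - mean(inputs)) / sd(inputs) *
      model$input_stats$sd + model$input_stats$mean
    inputs <- pmax(inputs, 0)
  }
  if (!is.null(train_envelopes)) {
    rep_ <- check_transfer_conditions(as.matrix(train_envelopes), inputs,
                                      tol = tol)
    if (!rep_$pass) {
      abort(paste0("Transfer conditions not met: ",
                   if (!rep_$bandwidth_ok)
                     sprintf("bandwidth %.2f vs %.2f Hz exceeds tol %.2f; ",
                             rep_$bw_source, rep_$bw_target, rep_$tol) else "",
                   if (!rep_$dims_ok) "dimension mismatch; " else ""),
            class = "lcasonify_transfer_error")
    }
  }
  vqvae_reconstruct(model, inputs)
}
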