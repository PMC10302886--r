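#' Partition-quality statistic gamma
#'
#' Trade-off between inter- and intra-class variability of a labeled point
#' set.  The first (silhouette) term is the mean over samples of
#' `(xi1 - xi0) / max(xi0, xi1)`, where `xi0` is the mean Euclidean
#' distance to the other points of the sample's own group and `xi1` the
#' mean distance to the points of the closest other group.  The second
#' (scatter) term is the mean squared distance of samples to their group
#' centers.  The default composition adds the two terms; the
#' `"silhouette"` variant reports the first term alone (the scatter term
#' grows with intra-class spread, so the additive composition is kept as
#' the verbatim default with the variant as an escape hatch).
#'
#' @param samples n x d matrix (or vector for 1-D).
#' @param groups per-row group labels (>= 2 groups, >= 1 sample each).
#' @param variant `"additive"` (default) or `"silhouette"`.
#' @return A `gamma_result`: list with `gamma`, `silhouette_term`,
#'   `scatter_term`, `n_groups`, `variant`.
#' @export
clustering_gamma <- function(samples, groups, variant = c("additive", "silhouette")) {
  variant <- match.arg(variant)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  groups <- as.character(groups)
  if (nrow(samples) != length(groups)) stop_param("samples/groups mismatch.")
  ug <- unique(groups)
  if (length(ug) < 2L) stop_param("Need >= 2 groups.")
  D <- as.matrix(stats::dist(samples))
  n <- nrow(samples)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(groups == groups[i])
    own <- setdiff(own, i)
    xi0 <- if (length(own) == 0L) 0 else mean(D[i, own])
    xi1 <- min(vapply(setdiff(ug, groups[i]), function(g) {
      mean(D[i, groups == g])
    }, numeric(1)))
    dn <- max(xi0, xi1)
    sil[i] <- if (dn == 0) 0 else (xi1 - xi0) / dn
  }
  scatter <- mean(vapply(seq_len(n), function(i) {
    ctrd <- colMeans(samples[groups == groups[i], , drop = FALSE])
    sum((samples[i, ] - ctrd)^2)
  }, numeric(1)))
  sil_term <- mean(sil)
  gamma <- if (variant == "additive") sil_term + scatter else sil_term
  structure(list(gamma = gamma, silhouette_term = sil_term,
                 scatter_term = scatter, n_groups = length(ug),
                 variant = variant),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> gamma = %.4f (silhouette %.4f + scatter %.4f, %d groups, %s)\n",
              x$gamma, x$silhouette_term, x$scatter_term, x$n_groups, x$variant))
  invisible(x)
}

#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, silhouette_term = x$silhouette_term,
                 scatter_term = x$scatter_term, n_groups = x$n_groups)
}

# gamma of the canonical variates of a fitted LCA, by label
lca_gamma <- function(fit, variant = "additive") {
  v <- scale(as.matrix(fit$variates[, c("u", "v")]))
  v[!is.finite(v)] <- 0
  clustering_gamma(v, fit$labels, variant = variant)
}

#' Leave-one-subject-out correlation confidence
#'
#' Fits the two-step alignment on all-but-one subject's pooled trials and
#' evaluates the canonical correlation on the held-out subject's projected
#' features; reports the per-fold r-squared with its mean and standard
#' deviation.
#'
#' @param per_subject list with one element per subject, each a list with
#'   `X` (matrix), `Y` (matrix), `labels`.
#' @param d,regularization,max_iter,seed passed to [lca()].
#' @param two_step use the CKA step (TRUE).
#' @return Tibble with one row per fold (`subject`, `r_squared`);
#'   attributes `mean` and `sd` summarize it.
#' @export
loso_correlation <- function(per_subject, d = NULL, regularization = 1e-3,
                             max_iter = 200L, seed = 1L, two_step = TRUE) {
  ns <- length(per_subject)
  if (ns < 2L) stop_param("Leave-one-subject-out needs >= 2 subjects.")
  r2 <- numeric(ns)
  for (k in seq_len(ns)) {
    train <- per_subject[-k]
    Xtr <- do.call(rbind, lapply(train, `[[`, "X"))
    Ytr <- do.call(rbind, lapply(train, `[[`, "Y"))
    ltr <- unlist(lapply(train, `[[`, "labels"))
    fit <- lca(Xtr, Ytr, ltr, d = d, regularization = regularization,
               two_step = two_step, max_iter = max_iter, seed = seed)
    ho <- per_subject[[k]]
    if (two_step) {
      Xt <- project_cka(fit$cka_x, ho$X)
      Yt <- project_cka(fit$cka_y, ho$Y)
    } else {
      Xt <- ho$X; Yt <- ho$Y
    }
    vv <- cca_variates(fit$cca, Xt, Yt)
    r2[k] <- suppressWarnings(cor(vv$u, vv$v))^2
    if (!is.finite(r2[k])) r2[k] <- 0
  }
  out <- tibble::tibble(subject = seq_len(ns), r_squared = r2)
  attr(out, "mean") <- mean(r2)
  attr(out, "sd") <- sd(r2)
  out
}

#' Dynamic resolution of a windowed correlation series
#'
#' Mean absolute difference between neighboring correlation values —
#' larger values mean faster time-varying dynamics.
#'
#' @param r_series numeric sequence of windowed r-squared values
#'   (length >= 2).
#' @return Scalar mean |r2(m+1) - r2(m)|.
#' @export
dynamic_resolution <- function(r_series) {
  if (length(r_series) < 2L) stop_param("Need a series of length >= 2.")
  mean(abs(diff(r_series)))
}

#' Sweep an analysis axis
#'
#' Re-runs feature extraction and the two-step alignment for every setting
#' along one axis and aggregates r-squared (mean and sd across labels) and
#' gamma of the canonical variates per setting.
#'
#' Axes: `"window"` (settings are tau values in seconds), `"band"`
#' (names into [eeg_bands()]), `"electrode_set"` (montage presets or
#' channel-drop lists), `"subject"` (subject ids; `eeg` must then be a
#' list of `eeg_epochs`).
#'
#' @param eeg an `eeg_epochs` object (or list of them for the subject
#'   axis).
#' @param stimuli list of audio waveforms aligned to trials, or a
#'   precomputed trials x Q matrix used as the audio block for every
#'   setting.
#' @param axis one of `"window"`, `"band"`, `"electrode_set"`,
#'   `"subject"`.
#' @param settings vector of settings for the axis; defaults to the study
#'   grid for `"window"` ({12, 6, 3, 1.5, 0.75, 0.375} s, capped at the
#'   trial length).
#' @param fs_audio sampling rate of `stimuli` waveforms.
#' @param tau window length used on non-window axes (trial length).
#' @param bands band set used on non-band axes (`"broadband"`).
#' @param measures FC measures (both).
#' @param d,regularization,max_iter,seed passed to [lca()].
#' @param gamma_variant passed to [clustering_gamma()].
#' @return A `sweep_result` tibble: one row per setting with `setting`,
#'   `r_squared_mean`, `r_squared_sd`, `gamma`.
#' @export
lca_sweep <- function(eeg, stimuli, axis = c("window", "band", "electrode_set", "subject"),
                      settings = NULL, fs_audio = NULL, tau = NULL,
                      bands = "broadband", measures = c("plv", "gfc"),
                      d = NULL, regularization = 1e-3, max_iter = 200L,
                      seed = 1L, gamma_variant = "additive") {
  axis <- match.arg(axis)
  base_eeg <- if (axis == "subject") eeg[[1L]] else eeg
  trial_length <- dim(base_eeg$data)[3L] / base_eeg$fs
  tau <- tau %||% trial_length
  settings <- settings %||% switch(axis,
    window = {
      g <- c(12, 6, 3, 1.5, 0.75, 0.375)
      g[g <= trial_length]
    },
    band = names(eeg_bands()),
    electrode_set = c("E17", "E14"),
    subject = seq_along(eeg))
  if (length(settings) == 0L) stop_param("No settings to sweep.")

  run_one <- function(setting) {
    this_eeg <- base_eeg
    this_tau <- tau
    this_bands <- bands
    if (axis == "window") this_tau <- as.numeric(setting)
    if (axis == "band") this_bands <- as.character(setting)
    if (axis == "electrode_set") this_eeg <- drop_channels(this_eeg, setting)
    if (axis == "subject") this_eeg <- eeg[[setting]]
    grid <- window_grid(this_tau, trial_length)
    fx <- extract_fc_features(this_eeg, grid, bands = this_bands,
                              measures = measures)
    Y <- if (is.matrix(stimuli)) stimuli else {
      assemble_audio_features(stimuli, fs_audio, window_grid(this_tau, trial_length),
                              n_phi = length(this_eeg$channel_names))$values
    }
    fit <- lca(fx, Y, d = d, regularization = regularization,
               max_iter = max_iter, seed = seed)
    per_label <- vapply(unique(fit$labels), function(l) {
      sub <- fit$variates[fit$labels == l, ]
      r <- suppressWarnings(cor(sub$u, sub$v))
      if (is.finite(r)) r^2 else 0
    }, numeric(1))
    g <- lca_gamma(fit, variant = gamma_variant)
    tibble::tibble(setting = as.character(setting),
                   r_squared = fit$r_squared,
                   r_squared_mean = mean(per_label),
                   r_squared_sd = sd(per_label),
                   gamma = g$gamma)
  }
  out <- dplyr::bind_rows(lapply(settings, run_one))
  class(out) <- c("sweep_result", class(out))
  attr(out, "axis") <- axis
  out
}
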