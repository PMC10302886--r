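#' Windowed acoustic descriptors
#'
#' Computes the 20-value descriptor vector for one audio segment:
#' zero-crossing rate, high/low energy ratio (1500 Hz split), spectral
#' entropy, spectral spread, spectral roll-off (85% energy), spectral
#' flatness, roughness (pairwise partial-interaction weights on spectral
#' peaks), RMS energy, broadband spectral flux, spectral centroid, and
#' spectral flux in ten octave-wide sub-bands anchored at 31.25 Hz.
#' Time-domain values (ZCR, RMS) use the raw samples; spectral values use
#' a Hann-tapered magnitude spectrum.  Flux terms need a previous frame's
#' spectrum and are 0 when none is supplied.
#'
#' @param segment numeric audio samples, length >= 256.
#' @param fs sampling rate in Hz.
#' @param prev_spectrum optional magnitude spectrum of the preceding frame
#'   (same length) for the flux terms.
#' @param split_hz high/low energy split frequency (1500).
#' @return Named numeric vector of length 20; attribute `"spectrum"`
#'   carries the magnitude spectrum for chaining flux computations.
#' @export
acoustic_descriptors <- function(segment, fs, prev_spectrum = NULL,
                                 split_hz = 1500) {
  n <- length(segment)
  if (n < 256L) stop_param("Audio segment too short (%d < 256 samples).", n)
  zcr <- mean(diff(sign(segment + 1e-300)) != 0)
  rms <- sqrt(mean(segment^2))

  spec <- Mod(fft(segment * hann_taper(n)))[seq_len(floor(n / 2) + 1L)]
  freqs <- (seq_along(spec) - 1L) * fs / n
  p <- spec^2
  ptot <- sum(p)
  if (ptot <= 0) {
    pn <- rep(0, length(p))
    centroid <- spread <- rolloff <- entropy <- 0
    flatness <- 0
    hl_ratio <- 0
  } else {
    pn <- p / ptot
    centroid <- sum(freqs * pn)
    spread <- sqrt(sum((freqs - centroid)^2 * pn))
    rolloff <- freqs[which(cumsum(pn) >= 0.85)[1L]]
    nz <- pn[pn > 0]
    entropy <- -sum(nz * log(nz)) / log(length(pn))
    # flatness on the magnitude spectrum (geometric / arithmetic mean)
    flatness <- if (mean(spec) > 0)
      exp(mean(log(spec + 1e-300))) / mean(spec) else 0
    hi <- sum(p[freqs >= split_hz])
    lo <- sum(p[freqs < split_hz])
    hl_ratio <- hi / (lo + 1e-300)
  }
  rough <- roughness(spec, freqs)

  if (is.null(prev_spectrum)) prev_spectrum <- spec
  d <- pmax(spec - prev_spectrum, 0)
  denom <- sum(spec) + 1e-300
  flux <- sum(d) / denom
  oct_edges <- 31.25 * 2^(0:10)
  oct_flux <- vapply(seq_len(10L), function(b) {
    inb <- freqs >= oct_edges[b] & freqs < oct_edges[b + 1L]
    sum(d[inb]) / denom
  }, numeric(1))

  out <- c(zcr = zcr, hl_energy_ratio = hl_ratio, spectral_entropy = entropy,
           spectral_spread = spread, spectral_rolloff = rolloff,
           spectral_flatness = flatness, roughness = rough, rms = rms,
           spectral_flux = flux, spectral_centroid = centroid,
           setNames(oct_flux, paste0("octave_flux_", seq_len(10L))))
  attr(out, "spectrum") <- spec
  out
}

# Plomp-Levelt-style roughness: pairwise interaction of the strongest
# spectral peaks, weighted by amplitude product and a dissonance curve of
# the normalized frequency separation.
roughness <- function(spec, freqs, n_peaks = 12L) {
  pk <- which(diff(sign(diff(spec))) == -2L) + 1L
  if (length(pk) < 2L) return(0)
  pk <- pk[order(spec[pk], decreasing = TRUE)][seq_len(min(n_peaks, length(pk)))]
  f <- freqs[pk]; a <- spec[pk] / max(spec[pk])
  tot <- 0
  for (i in seq_len(length(pk) - 1L)) {
    for (j in (i + 1L):length(pk)) {
      fmin <- min(f[i], f[j])
      s <- 0.24 / (0.021 * fmin + 19)
      x <- s * abs(f[i] - f[j])
      tot <- tot + a[i] * a[j] * (exp(-3.5 * x) - exp(-5.75 * x))
    }
  }
  tot
}

#' Per-frame descriptor trajectory for a window
#'
#' Slides fixed-size frames (2048 samples, 50% hop at 44.1 kHz by default)
#' across one analysis window and evaluates [acoustic_descriptors()] on
#' each, chaining spectra so the flux terms are between consecutive
#' frames.
#'
#' @param segment audio samples of one analysis window.
#' @param fs sampling rate in Hz.
#' @param frame_len frame size in samples (2048).
#' @param hop hop in samples (frame_len / 2).
#' @return frames x 20 matrix (at least one frame; short windows fall back
#'   to a single whole-window frame).
#' @export
descriptor_trajectory <- function(segment, fs, frame_len = 2048,
                                  hop = frame_len / 2) {
  n <- length(segment)
  if (n < frame_len * 2L) {
    return(matrix(acoustic_descriptors(segment, fs), nrow = 1L,
                  dimnames = list(NULL, names(acoustic_descriptors(segment, fs)))))
  }
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  prev <- NULL
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    d <- acoustic_descriptors(segment[starts[k]:(starts[k] + frame_len - 1L)],
                              fs, prev_spectrum = prev)
    prev <- attr(d, "spectrum")
    rows[[k]] <- as.numeric(d)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- names(acoustic_descriptors(segment[1:max(256, frame_len)], fs))
  out
}

#' Short-time auditory envelope
#'
#' Squares the waveform, smooths with a square (moving-average) window,
#' resamples to 64 Hz, and applies cubic-root compression.  For a
#' sinusoid of amplitude A the mid-signal envelope is (A^2/2)^(1/3).
#'
#' @param audio numeric waveform.
#' @param fs_in input sampling rate in Hz (> 128).
#' @param fs_out output rate (64 Hz).
#' @param smooth_sec moving-average length in seconds (0.125, passing
#'   amplitude modulation below roughly 8 Hz).
#' @return An `acoustic_envelope`: nonnegative numeric vector with
#'   attribute `fs`.
#' @export
acoustic_envelope <- function(audio, fs_in, fs_out = 64, smooth_sec = 0.125) {
  if (fs_in <= 128) stop_param("`fs_in` must exceed 128 Hz.")
  sq <- audio^2
  w <- max(1L, round(smooth_sec * fs_in))
  sm <- stats::filter(sq, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- sq[is.na(sm)]
  sm <- as.numeric(sm)
  t_old <- (seq_along(sm) - 1) / fs_in
  n_new <- max(2L, round(length(sm) * fs_out / fs_in))
  t_new <- (seq_len(n_new) - 1) / fs_out
  env <- approx(t_old, sm, xout = t_new, rule = 2)$y
  env <- pmax(env, 0)^(1 / 3)
  structure(env, fs = fs_out, class = c("acoustic_envelope", "numeric"))
}

#' First-principal-component summary of a descriptor trajectory
#'
#' Projects the frames x descriptors trajectory of one window onto its
#' first principal axis and returns the mean first-component score per
#' descriptor-block, i.e. one number per window per descriptor set; a
#' constant (zero-variance) trajectory returns 0 with a warning.
#'
#' When given a single descriptor's series (a vector), it is treated as a
#' frames x 1 trajectory.
#'
#' @param trajectory frames x d matrix (>= 2 frames) or numeric vector.
#' @return List with `scores` (per-frame first-component scores),
#'   `loading` (unit d-vector), `var_explained`, and `summary` (mean
#'   score, the per-window scalar).
#' @export
pca_first_component <- function(trajectory) {
  if (is.vector(trajectory)) trajectory <- matrix(trajectory, ncol = 1L)
  if (nrow(trajectory) < 2L) {
    warn("Single-frame trajectory has no variance; returning 0.")
    return(list(scores = rep(0, nrow(trajectory)),
                loading = rep(0, ncol(trajectory)),
                var_explained = 0, summary = 0))
  }
  ctr <- scale(trajectory, center = TRUE, scale = FALSE)
  if (all(abs(ctr) < 1e-12)) {
    warn("Constant trajectory has zero variance; returning 0.")
    return(list(scores = rep(0, nrow(trajectory)),
                loading = rep(0, ncol(trajectory)),
                var_explained = 0, summary = 0))
  }
  sv <- svd(ctr, nu = 1L, nv = 1L)
  loading <- sv$v[, 1L]
  # sign convention: largest-magnitude loading entry positive
  s <- sign(loading[which.max(abs(loading))])
  loading <- loading * s
  scores <- as.numeric(ctr %*% loading)
  ve <- sv$d[1L]^2 / sum(sv$d^2)
  list(scores = scores, loading = loading, var_explained = ve,
       summary = mean(scores) + as.numeric(colMeans(trajectory) %*% loading))
}

#' Assemble the audio feature matrix
#'
#' Per trial and analysis window: the 20 descriptors reduced over frames by
#' their first principal component (one score per descriptor), completed
#' with `n_phi - 1` samples drawn evenly from that window's 64-Hz
#' envelope, giving `Q = n_windows * (20 + n_phi - 1)` columns — sized to
#' match the EEG block.
#'
#' @param stimuli list of waveforms (one per trial), e.g. from
#'   [gen_audio_trials()].
#' @param fs sampling rate of the waveforms.
#' @param grid a [window_grid()] (in seconds; windows synchronize the two
#'   modalities).
#' @param n_phi number of EEG montage channels Nphi (sets the envelope
#'   sample count per window).
#' @param frame_len descriptor frame size in samples.
#' @return An `audio_features` object: list with `values`
#'   (trials x Q matrix), `index` tibble (feature, window, kind, name),
#'   and `envelopes` (list of `acoustic_envelope`).
#' @export
assemble_audio_features <- function(stimuli, fs, grid, n_phi,
                                    frame_len = 2048) {
  stopifnot(inherits(grid, "window_grid"))
  n_env <- n_phi - 1L
  wlen <- round(grid$tau * fs)
  hop <- round(grid$tau * (1 - grid$overlap) * fs)
  n_need <- hop * (grid$n_windows - 1L) + wlen
  rows <- vector("list", length(stimuli))
  envs <- vector("list", length(stimuli))
  for (tr in seq_along(stimuli)) {
    x <- stimuli[[tr]]
    if (length(x) < n_need) {
      stop_param("Stimulus %d (%d samples) shorter than the window grid (%d).",
                 tr, length(x), n_need)
    }
    env <- acoustic_envelope(x, fs)
    envs[[tr]] <- env
    fs_env <- attr(env, "fs")
    feats <- numeric(0)
    for (m in seq_len(grid$n_windows)) {
      s <- (m - 1L) * hop + 1L
      seg <- x[s:(s + wlen - 1L)]
      traj <- descriptor_trajectory(seg, fs, frame_len = frame_len)
      desc <- vapply(seq_len(ncol(traj)), function(j) {
        tj <- traj[, j]
        if (nrow(traj) < 2L || sd(tj) < 1e-14) mean(tj)
        else pca_first_component(tj)$summary
      }, numeric(1))
      t0 <- (s - 1L) / fs
      t1 <- (s + wlen - 2L) / fs
      i0 <- max(1L, floor(t0 * fs_env) + 1L)
      i1 <- min(length(env), ceiling(t1 * fs_env) + 1L)
      pick <- unique(round(seq(i0, i1, length.out = n_env)))
      ev <- as.numeric(env)[pick]
      if (length(ev) < n_env) ev <- rep_len(ev, n_env)
      feats <- c(feats, desc, ev)
    }
    rows[[tr]] <- feats
  }
  values <- do.call(rbind, rows)
  dn <- colnames(descriptor_trajectory(stimuli[[1L]][seq_len(min(4096, length(stimuli[[1L]])))], fs))
  index <- dplyr::bind_rows(lapply(seq_len(grid$n_windows), function(m) {
    tibble::tibble(window = m,
                   kind = c(rep("descriptor", 20L), rep("envelope", n_env)),
                   name = c(dn, paste0("env_", seq_len(n_env))))
  }))
  index <- dplyr::mutate(index, feature = dplyr::row_number(), .before = 1L)
  structure(list(values = values, index = index, envelopes = envs,
                 grid = grid, n_phi = n_phi),
            class = "audio_features")
}

#' @export
print.audio_features <- function(x, ...) {
  cat(sprintf("<audio_features> %d trials x %d features (%d windows x (20 + %d envelope samples))\n",
              nrow(x$values), ncol(x$values), x$grid$n_windows, x$n_phi - 1L))
  invisible(x)
}
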