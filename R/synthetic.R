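#' Specification for synthetic coupled EEG/audio data
#'
#' Collects the ground-truth parameters of the generator: trial counts and
#' lengths matching the affective music-listening paradigm (40 trials of
#' 12 s per subject, 19-channel 10-20 montage, four arousal-valence
#' quadrant labels), planted narrowband phase coupling between named
#' channel pairs per label, a planted first canonical correlation between
#' the abstract feature blocks, and label-informative feature columns.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_subject trials per subject (40).
#' @param n_channels montage size; 19 uses the standard 10-20 names.
#' @param channel_names optional explicit channel names (length
#'   `n_channels`), e.g. a 10-20 subset for reduced montages.
#' @param fs_eeg EEG sampling rate in Hz (raw recordings are 1000 Hz).
#' @param trial_length trial length T in seconds (12).
#' @param labels the four quadrant labels HAPV/HANV/LANV/LAPV.
#' @param coupled_pairs data frame with columns `ch1`, `ch2`, `label`:
#'   channel pairs sharing a narrowband oscillator on trials of `label`;
#'   an optional `amp` column scales the oscillator per entry (so one pair
#'   can be coupled with a different strength under each label).
#' @param coupling_freq oscillator frequency in Hz (10, alpha band).
#' @param coupling_lag fixed phase lag in radians between the pair.
#' @param coupling_amp oscillator amplitude.
#' @param coupling_jitter sd of a per-trial multiplicative amplitude latent
#'   (0 disables); the latent is returned as attribute `"trial_latent"`.
#' @param planted_rho population first canonical correlation in \[0,1\] for
#'   [gen_coupled_features()].
#' @param relevant_feature_idx columns of X carrying label mean shifts.
#' @param noise_sd additive white-noise standard deviation (>= 0; 0 gives
#'   the noiseless phase-locking limit).
#' @param amp_mix strength of the label-dependent channel mixing that
#'   plants amplitude covariance (visible to Gaussian FC, not to PLV).
#' @param seed integer seed; identical seeds give bit-identical data.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(n_subjects = 1,
                          n_trials_per_subject = 40,
                          n_channels = 19,
                          channel_names = NULL,
                          fs_eeg = 1000,
                          trial_length = 12,
                          labels = c("HAPV", "HANV", "LANV", "LAPV"),
                          coupled_pairs = NULL,
                          coupling_freq = 10,
                          coupling_lag = pi / 4,
                          coupling_amp = 1,
                          coupling_jitter = 0,
                          planted_rho = 0.8,
                          relevant_feature_idx = integer(),
                          noise_sd = 1,
                          amp_mix = 0.5,
                          seed = 1L) {
  check_scalar_number(planted_rho, "planted_rho", 0, 1)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(fs_eeg, "fs_eeg", lower = 1)
  if (length(labels) < 1L) stop_param("`labels` must be non-empty.")
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 19L) montage_1020() else
      paste0("Ch", seq_len(n_channels))
  } else if (length(channel_names) != n_channels) {
    stop_param("`channel_names` must have length n_channels.")
  }
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- as.data.frame(coupled_pairs)
    stopifnot(all(c("ch1", "ch2", "label") %in% names(coupled_pairs)))
    bad <- setdiff(c(coupled_pairs$ch1, coupled_pairs$ch2), channel_names)
    if (length(bad) > 0L) {
      stop_param("Coupled pair channel(s) outside the montage: %s",
                 paste(unique(bad), collapse = ", "))
    }
    if (!all(coupled_pairs$label %in% labels)) {
      stop_param("Coupled pair label outside the label set.")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    n_channels = as.integer(n_channels),
    channel_names = channel_names,
    fs_eeg = fs_eeg, trial_length = trial_length,
    labels = labels, coupled_pairs = coupled_pairs,
    coupling_freq = coupling_freq, coupling_lag = coupling_lag,
    coupling_amp = coupling_amp, coupling_jitter = coupling_jitter,
    planted_rho = planted_rho,
    relevant_feature_idx = as.integer(relevant_feature_idx),
    noise_sd = noise_sd, amp_mix = amp_mix, seed = as.integer(seed)
  ), class = "coupling_spec")
}

#' Generate EEG-like epochs with planted phase coupling
#'
#' Each trial is white noise mixed through a label-specific channel matrix
#' (planting label-dependent amplitude covariance) plus, for channel pairs
#' listed for the trial's label, a shared narrowband sinusoid with a random
#' per-trial initial phase and a fixed lag between the two channels.  In the
#' zero-noise limit the phase-locking value of a planted pair is exactly 1.
#'
#' @param spec a [coupling_spec()].
#' @return An [eeg_epochs()] object (one subject; for several subjects a
#'   list of them).  Attribute `"trial_latent"` holds the per-trial
#'   coupling-amplitude latent when `coupling_jitter > 0`.
#' @export
gen_eeg_trials <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  subjects <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) gen_one_subject(spec, s))
  })
  if (spec$n_subjects == 1L) subjects[[1L]] else subjects
}

gen_one_subject <- function(spec, s) {
  nr <- spec$n_trials_per_subject
  nc <- spec$n_channels
  ns <- round(spec$trial_length * spec$fs_eeg)
  tt <- (seq_len(ns) - 1) / spec$fs_eeg
  labels <- rep_len(spec$labels, nr)
  # per-label mixing matrices: I + amp_mix * R, R fixed across trials
  mixers <- lapply(seq_along(spec$labels), function(i) {
    R <- matrix(rnorm(nc * nc, sd = 1 / sqrt(nc)), nc, nc)
    diag(nc) + spec$amp_mix * R
  })
  names(mixers) <- spec$labels
  latent <- if (spec$coupling_jitter > 0) rnorm(nr) else rep(0, nr)
  data <- array(0, c(nr, nc, ns))
  for (tr in seq_len(nr)) {
    lab <- labels[tr]
    noise <- matrix(rnorm(nc * ns, sd = spec$noise_sd), nc, ns)
    x <- if (spec$noise_sd > 0) mixers[[lab]] %*% noise else noise
    if (!is.null(spec$coupled_pairs)) {
      pairs <- spec$coupled_pairs[spec$coupled_pairs$label == lab, ,
                                  drop = FALSE]
      if (nrow(pairs) > 0L) {
        base_amp <- spec$coupling_amp *
          exp(spec$coupling_jitter * latent[tr])
        for (p in seq_len(nrow(pairs))) {
          amp <- if (!is.null(pairs$amp)) base_amp * pairs$amp[p] else base_amp
          phi0 <- runif(1, 0, 2 * pi)
          i <- match(pairs$ch1[p], spec$channel_names)
          j <- match(pairs$ch2[p], spec$channel_names)
          x[i, ] <- x[i, ] + amp * sin(2 * pi * spec$coupling_freq * tt + phi0)
          x[j, ] <- x[j, ] + amp * sin(2 * pi * spec$coupling_freq * tt + phi0 -
                                         spec$coupling_lag)
        }
      }
    }
    data[tr, , ] <- x
  }
  out <- eeg_epochs(data, spec$fs_eeg, spec$channel_names, labels,
                    subject_id = sprintf("S%02d", s))
  attr(out, "trial_latent") <- latent
  out
}

#' Generate label-templated audio stimuli
#'
#' Each label is assigned a distinct amplitude-envelope template (different
#' attack/decay shapes) modulating a fixed harmonic carrier; small seeded
#' within-label jitter perturbs gain and attack time.
#'
#' @param labels per-trial label vector.
#' @param fs audio sampling rate in Hz (44100 in the study).
#' @param seed integer seed.
#' @param trial_length clip length in seconds (12).
#' @param f0 carrier fundamental in Hz.
#' @param jitter within-label relative jitter (0 disables).
#' @return List of numeric waveforms, one per trial, each of length
#'   `trial_length * fs` samples; attribute `"labels"` echoes the labels.
#' @export
gen_audio_trials <- function(labels, fs = 44100, seed = 1L,
                             trial_length = 12, f0 = 220, jitter = 0.05) {
  if (length(labels) == 0L) stop_param("`labels` must be non-empty.")
  check_scalar_number(fs, "fs", lower = 1)
  n <- round(trial_length * fs)
  tt <- (seq_len(n) - 1) / fs
  ulab <- sort(unique(labels))
  carrier <- {
    h <- c(1, 0.5, 0.25)
    rowSums(sapply(seq_along(h), function(k) h[k] * sin(2 * pi * k * f0 * tt)))
  }
  carrier <- carrier / max(abs(carrier))
  waves <- withr::with_seed(as.integer(seed), {
    lapply(seq_along(labels), function(i) {
      li <- match(labels[i], ulab)
      g <- 1 + jitter * rnorm(1)
      a <- max(0.02, label_attack(li) * (1 + jitter * rnorm(1)))
      env <- label_envelope_template(li, tt, trial_length, attack = a)
      g * env * carrier
    })
  })
  attr(waves, "labels") <- labels
  attr(waves, "fs") <- fs
  waves
}

# Distinct attack times (s) and decay behaviours per label index.
label_attack <- function(li) c(0.1, 0.6, 1.5, 3)[(li - 1L) %% 4L + 1L]

label_envelope_template <- function(li, tt, trial_length, attack) {
  decay_rate <- c(0.05, 0.2, 0.4, 0.02)[(li - 1L) %% 4L + 1L]
  mod_freq <- c(0, 1, 2, 0.5)[(li - 1L) %% 4L + 1L]
  env <- pmin(tt / attack, 1) * exp(-decay_rate * pmax(tt - attack, 0))
  if (mod_freq > 0) env <- env * (0.8 + 0.2 * sin(2 * pi * mod_freq * tt))
  env
}

#' Generate coupled feature blocks with known canonical correlation
#'
#' Plants one shared standard-normal latent into the first column of each
#' block so the population first canonical correlation equals `rho`
#' (`x1 = sqrt(rho) z + sqrt(1-rho) e`, likewise for `y1`, both
#' unit-variance, so cor(x1, y1) = rho).  A disjoint column subset of X
#' carries per-label mean shifts of size `label_sep`; all remaining columns
#' are isotropic standard normal noise.
#'
#' @param n number of rows (trials).
#' @param P,Q numbers of columns in X and Y.
#' @param rho planted population canonical correlation in \[0, 1\].
#' @param label_sep label mean-shift magnitude on the informative columns
#'   of X (0 disables).
#' @param seed integer seed.
#' @param n_labels number of label categories (4).
#' @param n_informative number of label-informative X columns (2), placed
#'   right after the shared-latent column.
#' @param latent_label_sep optional label mean shift applied to the shared
#'   latent itself, making the canonical pair label-separated (0 keeps the
#'   planted `rho` exact).
#' @param x_profile optional unit-norm P-vector distributing the shared
#'   latent across the columns of X (e.g. a smooth profile over a window
#'   axis); `NULL` plants it in column 1 only, which keeps the population
#'   canonical correlation exactly `rho`.  A distributed profile keeps it
#'   approximately `rho` (each column stays unit-variance).
#' @return List with matrices `X` (n x P), `Y` (n x Q), character vector
#'   `labels`, and ground-truth index vectors `shared_cols_x`,
#'   `shared_cols_y`, `informative_cols_x`.
#' @export
gen_coupled_features <- function(n, P, Q, rho, label_sep = 0, seed = 1L,
                                 n_labels = 4, n_informative = 2,
                                 latent_label_sep = 0, x_profile = NULL) {
  check_scalar_number(rho, "rho", 0, 1)
  if (P < 1L || Q < 1L) stop_param("P and Q must be >= 1.")
  n_informative <- min(n_informative, max(P - 1L, 0L))
  withr::with_seed(as.integer(seed), {
    labels <- paste0("L", rep_len(seq_len(n_labels), n))
    z <- rnorm(n)
    if (latent_label_sep > 0) {
      shift <- latent_label_sep * (match(labels, unique(labels)) -
                                     (n_labels + 1) / 2) / n_labels
      z <- z + shift
    }
    X <- matrix(rnorm(n * P), n, P)
    Y <- matrix(rnorm(n * Q), n, Q)
    if (is.null(x_profile)) {
      X[, 1L] <- sqrt(rho) * z + sqrt(1 - rho) * X[, 1L]
    } else {
      if (length(x_profile) != P) stop_param("`x_profile` must have length P.")
      l <- x_profile / sqrt(sum(x_profile^2))
      for (j in seq_len(P)) {
        X[, j] <- sqrt(rho) * l[j] * z + sqrt(max(1 - rho * l[j]^2, 0)) * X[, j]
      }
    }
    Y[, 1L] <- sqrt(rho) * z + sqrt(1 - rho) * Y[, 1L]
    info <- if (n_informative > 0L) 1L + seq_len(n_informative) else integer()
    for (j in info) {
      X[, j] <- X[, j] + label_sep *
        ((match(labels, unique(labels)) - (n_labels + 1) / 2) / n_labels) *
        (if (j %% 2L == 0L) 1 else -1)
    }
    list(X = X, Y = Y, labels = labels,
         shared_cols_x = 1L, shared_cols_y = 1L,
         informative_cols_x = info)
  })
}
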