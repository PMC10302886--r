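#' Epoched EEG container
#'
#' Bundles a trials x channels x samples array with its sampling rate,
#' channel names (10-20 system), per-trial emotion labels from the
#' arousal-valence quadrants, and a subject identifier.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param labels per-trial labels (character or factor), one per trial.
#' @param subject_id identifier for the recording subject.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, channel_names, labels,
                       subject_id = "S01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_param("`data` must be a trials x channels x samples array.")
  }
  check_scalar_number(fs, "fs", lower = .Machine$double.eps)
  if (length(channel_names) != dim(data)[2L]) {
    stop_param("`channel_names` length (%d) != channel dimension (%d).",
               length(channel_names), dim(data)[2L])
  }
  if (length(labels) != dim(data)[1L]) {
    stop_param("`labels` length (%d) != trial dimension (%d).",
               length(labels), dim(data)[1L])
  }
  structure(
    list(data = data, fs = fs,
         channel_names = as.character(channel_names),
         labels = as.character(labels),
         subject_id = subject_id),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  cat("  labels:  ", paste(names(table(x$labels)),
                           table(x$labels), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Standard 10-20 montage used throughout
#'
#' The 19-electrode layout of the affective music-listening montage.
#' @return character vector of 19 channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering; the default
#' third-order design applied in both directions has an effective
#' sixth-order magnitude response.
#'
#' @param x numeric signal, or an `eeg_epochs` object (filtered per
#'   trial and channel).
#' @param low,high band edges in Hz; defaults 1 and 45.
#' @param fs sampling rate (taken from the object for `eeg_epochs`).
#' @param order filter order before the forward-backward pass; default 3.
#' @return Filtered object of the same shape/class.
#' @export
bandpass <- function(x, low = 1, high = 45, fs = NULL, order = 3) {
  if (inherits(x, "eeg_epochs")) {
    fs <- x$fs
    flt <- design_bandpass(low, high, fs, order)
    x$data <- apply_channelwise(x$data, function(v) signal::filtfilt(flt, v))
    return(x)
  }
  if (is.null(fs)) stop_param("`fs` is required for plain numeric input.")
  flt <- design_bandpass(low, high, fs, order)
  signal::filtfilt(flt, x)
}

design_bandpass <- function(low, high, fs, order) {
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop_param("Band edges must satisfy 0 < low < high < fs/2 (got [%g, %g] at fs=%g).",
               low, high, fs)
  }
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

apply_channelwise <- function(arr, f) {
  d <- dim(arr)
  out <- arr
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[tr, ch, ] <- f(arr[tr, ch, ])
    }
  }
  out
}

#' Drop channels from a montage
#'
#' Removes channels by name. Two presets mirror the montages used for the
#' electrode-set comparison: `"E17"` drops the occipital pair (O1, O2)
#' from the 19-channel layout, and `"E14"` additionally drops the
#' frontopolar pair (Fp1, Fp2) and midline parietal Pz.
#'
#' @param eeg an `eeg_epochs` object.
#' @param names character vector of channel names to drop, or a preset
#'   (`"E17"`, `"E14"`).
#' @return `eeg_epochs` without the listed channels.
#' @export
drop_channels <- function(eeg, names) {
  stopifnot(inherits(eeg, "eeg_epochs"))
  if (length(names) == 1L && names %in% c("E17", "E14")) {
    names <- switch(names,
                    E17 = c("O1", "O2"),
                    E14 = c("O1", "O2", "Fp1", "Fp2", "Pz"))
    names <- intersect(names, eeg$channel_names)
  }
  if (length(names) == 0L) return(eeg)
  missing <- setdiff(names, eeg$channel_names)
  if (length(missing) > 0L) {
    stop_param("Unknown channel(s): %s", paste(missing, collapse = ", "))
  }
  keep <- !(eeg$channel_names %in% names)
  eeg$data <- eeg$data[, keep, , drop = FALSE]
  eeg$channel_names <- eeg$channel_names[keep]
  eeg
}

#' Common-average re-referencing
#'
#' Subtracts the per-sample mean across channels from every channel, so the
#' channel sum is zero at each sample.
#'
#' @param eeg an `eeg_epochs` object with at least two channels.
#' @return Re-referenced `eeg_epochs`.
#' @export
common_average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_epochs"))
  if (dim(eeg$data)[2L] < 2L) {
    stop_param("Common-average referencing needs >= 2 channels.")
  }
  for (tr in seq_len(dim(eeg$data)[1L])) {
    m <- colMeans(eeg$data[tr, , , drop = TRUE])
    eeg$data[tr, , ] <- sweep(eeg$data[tr, , , drop = TRUE], 2L, m)
  }
  eeg
}

#' Resample epochs to a lower rate
#'
#' Anti-alias filters (zero-phase Butterworth lowpass at 0.45 of the target
#' rate) and then interpolates each trial/channel onto the new sample grid.
#'
#' @param eeg an `eeg_epochs` object.
#' @param fs_new target rate in Hz, must be below the current rate.
#' @return `eeg_epochs` at `fs_new`.
#' @export
resample_epochs <- function(eeg, fs_new = 80) {
  stopifnot(inherits(eeg, "eeg_epochs"))
  if (fs_new >= eeg$fs) stop_param("`fs_new` (%g) must be < fs (%g).", fs_new, eeg$fs)
  d <- dim(eeg$data)
  n_old <- d[3L]
  n_new <- round(n_old * fs_new / eeg$fs)
  flt <- signal::butter(6, 0.9 * fs_new / eeg$fs, type = "low")
  t_old <- (seq_len(n_old) - 1) / eeg$fs
  t_new <- (seq_len(n_new) - 1) / fs_new
  out <- array(0, c(d[1L], d[2L], n_new))
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      y <- signal::filtfilt(flt, eeg$data[tr, ch, ])
      out[tr, ch, ] <- approx(t_old, y, xout = t_new, rule = 2)$y
    }
  }
  eeg$data <- out
  eeg$fs <- fs_new
  eeg
}

#' Overlapping-window grid
#'
#' Describes the piecewise-stationary segmentation: window length `tau`
#' seconds, 50% overlap by default, Hann taper.  The number of full windows
#' in a trial of length `T` is `floor((T - tau) / (tau * (1 - overlap))) + 1`;
#' short trailing remainders are discarded.
#'
#' @param tau window length in seconds; the study grid is
#'   {12, 6, 3, 1.5, 0.75, 0.375}.
#' @param trial_length trial length `T` in seconds (12 by default).
#' @param overlap fractional overlap between consecutive windows (0.5).
#' @param taper taper name; only `"hann"` is implemented.
#' @return A `window_grid` list with `tau`, `overlap`, `taper`,
#'   `trial_length`, and the window count `n_windows`.
#' @export
window_grid <- function(tau, trial_length = 12, overlap = 0.5, taper = "hann") {
  check_scalar_number(tau, "tau", lower = .Machine$double.eps)
  if (tau > trial_length) {
    stop_param("`tau` (%g s) exceeds the trial length (%g s).", tau, trial_length)
  }
  taper <- match.arg(taper)
  n_windows <- floor((trial_length - tau) / (tau * (1 - overlap))) + 1L
  structure(list(tau = tau, trial_length = trial_length, overlap = overlap,
                 taper = taper, n_windows = as.integer(n_windows)),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> tau=%g s, overlap=%g, %s taper: %d windows in %g s\n",
              x$tau, x$overlap, x$taper, x$n_windows, x$trial_length))
  invisible(x)
}

#' Cut one trial into tapered overlapping segments
#'
#' @param epoch channels x samples matrix (or a numeric vector for a single
#'   channel).
#' @param grid a [window_grid()].
#' @param fs sampling rate in Hz.
#' @return List of `n_windows` Hann-tapered matrices (channels x window
#'   samples).
#' @export
window_segments <- function(epoch, grid, fs) {
  stopifnot(inherits(grid, "window_grid"))
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  n <- ncol(epoch)
  wlen <- round(grid$tau * fs)
  hop <- round(grid$tau * (1 - grid$overlap) * fs)
  taper <- hann_taper(wlen)
  starts <- seq(1L, by = hop, length.out = grid$n_windows)
  if (starts[grid$n_windows] + wlen - 1L > n) {
    stop_param("Window grid (%d windows of %d samples) does not fit %d samples.",
               grid$n_windows, wlen, n)
  }
  lapply(starts, function(s) {
    seg <- epoch[, s:(s + wlen - 1L), drop = FALSE]
    sweep(seg, 2L, taper, `*`)
  })
}

# Periodic Hann window with peak value 1 at the midpoint for even n
# (0.5 - 0.5 cos(2 pi k / n), k = 0..n-1).
hann_taper <- function(n) {
  k <- seq_len(n) - 1L
  0.5 - 0.5 * cos(2 * pi * k / n)
}

#' Full EEG conditioning chain
#'
#' Applies, in order: broadband bandpass, channel removal, common-average
#' referencing, and downsampling.  Band-limited copies for the
#' theta/alpha/beta rhythms are produced downstream by re-running the same
#' Butterworth design per band (see [extract_fc_features()]).
#'
#' @param eeg an `eeg_epochs` object (already epoched at stimulus onset).
#' @param band broadband edges in Hz, default `c(1, 45)`.
#' @param montage `"E17"`, `"E14"`, a character vector of channels to drop,
#'   or `NULL` to keep all channels.
#' @param fs_out target rate after downsampling (80 Hz), or `NULL` to skip.
#' @return Conditioned `eeg_epochs`.
#' @export
preprocess_eeg <- function(eeg, band = c(1, 45), montage = "E17",
                           fs_out = 80) {
  eeg <- bandpass(eeg, band[1], band[2])
  if (!is.null(montage)) eeg <- drop_channels(eeg, montage)
  eeg <- common_average_reference(eeg)
  if (!is.null(fs_out) && fs_out < eeg$fs) eeg <- resample_epochs(eeg, fs_out)
  eeg
}

#' Named frequency bands for rhythm-specific extraction
#'
#' @return Named list of band edges in Hz: broadband 1-45, theta 4-8,
#'   alpha 8-12, beta 12-30.
#' @export
eeg_bands <- function() {
  list(broadband = c(1, 45), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}
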