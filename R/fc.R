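#' Instantaneous phase via the analytic signal
#'
#' Phase of the analytic signal built with the Hilbert-transform
#' construction (FFT method).  Meaningful for narrowband input; the
#' band-limited, Hann-tapered windows produced by the preprocessing chain
#' satisfy this.
#'
#' @param x numeric signal, length >= 8, not all zero.
#' @return Phase series in radians (wrapped; only differences are used
#'   downstream).
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 8L) stop_param("Signal too short for phase estimation (< 8 samples).")
  if (all(x == 0)) stop_param("All-zero signal has no defined phase.")
  Arg(analytic_signal(x))
}

analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Phase Locking Value
#'
#' Modulus of the time-averaged unit phasor of the instantaneous phase
#' difference between two equal-length signals:
#' `|E[exp(j(phi_1(t) - phi_2(t)))]|`.  The value is 1 for a constant lag
#' and near 0 for independent phases.  Analytic-signal edge distortion is
#' handled by excluding a fraction of samples at each end.
#'
#' @param x,y numeric signals of equal length.
#' @param edge_trim fraction of samples dropped at each end (0.05).
#' @return PLV in \[0, 1\].
#' @export
plv <- function(x, y, edge_trim = 0.05) {
  if (length(x) != length(y)) stop_param("PLV inputs must have equal length.")
  dphi <- instantaneous_phase(x) - instantaneous_phase(y)
  n <- length(dphi)
  keep <- seq.int(floor(n * edge_trim) + 1L, n - floor(n * edge_trim))
  plv_from_phase_diff(dphi[keep])
}

# Rayleigh-type statistic on a phase-difference series.
plv_from_phase_diff <- function(dphi) {
  Mod(mean(exp(1i * dphi)))
}

#' Gaussian functional connectivity
#'
#' Gaussian-kernel similarity between two windowed channel time series:
#' `exp(-||x - y||^2 / (2 sigma^2))`.  Unlike the phase-locking value it is
#' sensitive to amplitude, which is what lets it see planted amplitude
#' covariance.
#'
#' @param x,y numeric signals of equal length.
#' @param sigma positive length-scale hyperparameter.
#' @return Similarity in (0, 1].
#' @export
gfc <- function(x, y, sigma) {
  if (length(x) != length(y)) stop_param("GFC inputs must have equal length.")
  check_scalar_number(sigma, "sigma", lower = .Machine$double.eps)
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Select the Gaussian-FC bandwidth
#'
#' Picks the grid value maximizing the variance of the off-diagonal GFC
#' values over all channel pairs and windows (`argmax var`).  Tiny sigma
#' drives every value to 0 and huge sigma to 1, so the maximizer is
#' interior; a degenerate case (single pair, or zero variance everywhere)
#' falls back to the grid median with a warning.
#'
#' @param windows list of channels x samples matrices (tapered windows), or
#'   a single matrix.
#' @param grid candidate sigmas; default 20 log-spaced values spanning
#'   0.1x to 10x the median pairwise distance.
#' @param scale z-score each channel before computing distances (TRUE,
#'   matching the GFC matrix construction).
#' @return The selected sigma (attribute `"variance"` holds the profile).
#' @export
select_bandwidth <- function(windows, grid = NULL, scale = TRUE) {
  if (is.matrix(windows)) windows <- list(windows)
  dists <- unlist(lapply(windows, function(w) {
    if (scale) w <- t(scale(t(w)))
    as.vector(stats::dist(w))
  }))
  dists <- dists[is.finite(dists)]
  if (length(dists) == 0L) stop_param("No channel pairs to evaluate.")
  if (is.null(grid)) {
    md <- median(dists)
    if (md <= 0) md <- 1
    grid <- exp(seq(log(0.1 * md), log(10 * md), length.out = 20L))
  }
  if (length(grid) == 0L || any(grid <= 0)) {
    stop_param("`grid` must be non-empty and positive.")
  }
  vars <- vapply(grid, function(s) var(exp(-dists^2 / (2 * s^2))), numeric(1))
  vars[is.na(vars)] <- 0
  if (all(vars == 0)) {
    warn("Degenerate GFC variance profile; returning the grid median.")
    out <- median(grid)
  } else {
    out <- grid[which.max(vars)]
  }
  attr(out, "variance") <- vars
  out
}

#' Connectivity matrix for one window
#'
#' Fills all unordered channel pairs with the requested measure, sets the
#' diagonal to 1, and is symmetric by construction.  For GFC, channels are
#' z-scored before the distance so the measure is not dominated by
#' amplitude offsets.
#'
#' @param window channels x samples matrix (a tapered, band-limited
#'   window).
#' @param measure `"plv"` or `"gfc"`.
#' @param sigma GFC bandwidth (required for `"gfc"`).
#' @param edge_trim passed to [plv()].
#' @return A `connectivity_matrix`: the matrix with attributes `measure`
#'   and `channel_names` (if the input had rownames).
#' @export
connectivity_matrix <- function(window, measure = c("plv", "gfc"),
                                sigma = NULL, edge_trim = 0.05) {
  measure <- match.arg(measure)
  if (nrow(window) < 2L) stop_param("Need >= 2 channels for connectivity.")
  nc <- nrow(window)
  M <- diag(1, nc)
  if (measure == "plv") {
    ph <- t(apply(window, 1L, function(v) {
      if (all(v == 0)) rep(0, length(v)) else Arg(analytic_signal(v))
    }))
    n <- ncol(ph)
    keep <- seq.int(floor(n * edge_trim) + 1L, n - floor(n * edge_trim))
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        M[i, j] <- M[j, i] <- plv_from_phase_diff(ph[i, keep] - ph[j, keep])
      }
    }
  } else {
    if (is.null(sigma)) stop_param("GFC requires `sigma`.")
    w <- t(scale(t(window)))
    w[!is.finite(w)] <- 0
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        M[i, j] <- M[j, i] <- gfc(w[i, ], w[j, ], sigma)
      }
    }
  }
  rn <- rownames(window)
  structure(M, measure = measure, channel_names = rn,
            class = c("connectivity_matrix", "matrix", "array"))
}

# Strict-upper-triangle vectorization, row-major: (1,2), (1,3), ..., (n-1,n).
pair_index <- function(channel_names) {
  nc <- length(channel_names)
  idx <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(ch1 = channel_names[idx[, 1L]],
                 ch2 = channel_names[idx[, 2L]],
                 i = idx[, 1L], j = idx[, 2L])
}

vectorize_upper <- function(M) {
  nc <- nrow(M)
  out <- numeric(nc * (nc - 1L) / 2L)
  k <- 1L
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      out[k] <- M[i, j]
      k <- k + 1L
    }
  }
  out
}

#' Extract the EEG functional-connectivity feature matrix
#'
#' For every trial, frequency band, window and measure, computes the
#' connectivity matrix and vectorizes its strict upper triangle
#' (`NFC = Nphi (Nphi - 1) / 2` values per matrix).  Columns are ordered by
#' (measure, band, window, pair) and described in a feature-index tibble,
#' so the arrangement doubles in size when both measures are requested.
#'
#' @param eeg a preprocessed [eeg_epochs()] object.
#' @param grid a [window_grid()] (its `trial_length` should match the
#'   epochs).
#' @param bands named list of band edges in Hz, or names into
#'   [eeg_bands()]; `"broadband"` skips the extra filtering pass.
#' @param measures character subset of `c("plv", "gfc")`.
#' @param sigma GFC bandwidth; `NULL` selects it per band via
#'   [select_bandwidth()] on the first trial's windows.
#' @param edge_trim passed to [plv()].
#' @return An `fc_features` object: list with `values` (trials x P matrix),
#'   `index` (tibble: feature, measure, band, window, ch1, ch2), `labels`,
#'   `subject_id`, and the sigmas used.
#' @export
extract_fc_features <- function(eeg, grid, bands = "broadband",
                                measures = c("plv", "gfc"),
                                sigma = NULL, edge_trim = 0.05) {
  stopifnot(inherits(eeg, "eeg_epochs"), inherits(grid, "window_grid"))
  if (length(measures) == 0L) stop_param("`measures` must be non-empty.")
  measures <- match.arg(measures, c("plv", "gfc"), several.ok = TRUE)
  if (is.character(bands)) {
    if (length(bands) == 0L) stop_param("`bands` must be non-empty.")
    bands <- eeg_bands()[match.arg(bands, names(eeg_bands()),
                                   several.ok = TRUE)]
  }
  if (length(bands) == 0L) stop_param("`bands` must be non-empty.")
  nr <- dim(eeg$data)[1L]
  nc <- dim(eeg$data)[2L]
  pidx <- pair_index(eeg$channel_names)
  nfc <- nrow(pidx)

  # Band-limited copies of the data (broadband = as-is).
  band_data <- lapply(names(bands), function(b) {
    if (identical(b, "broadband")) return(eeg$data)
    flt <- design_bandpass(bands[[b]][1], bands[[b]][2], eeg$fs, 3)
    apply_channelwise(eeg$data, function(v) signal::filtfilt(flt, v))
  })
  names(band_data) <- names(bands)

  # Window each trial once per band.
  windows <- lapply(band_data, function(arr) {
    lapply(seq_len(nr), function(tr) {
      window_segments(arr[tr, , , drop = TRUE], grid, eeg$fs)
    })
  })

  sigmas <- setNames(numeric(length(bands)), names(bands))
  if ("gfc" %in% measures) {
    for (b in names(bands)) {
      sigmas[b] <- if (is.null(sigma)) {
        as.numeric(select_bandwidth(windows[[b]][[1L]]))
      } else sigma
    }
  }

  blocks <- list()
  index <- list()
  for (ms in measures) {
    for (b in names(bands)) {
      for (m in seq_len(grid$n_windows)) {
        mat <- matrix(0, nr, nfc)
        for (tr in seq_len(nr)) {
          C <- connectivity_matrix(windows[[b]][[tr]][[m]], ms,
                                   sigma = if (ms == "gfc") sigmas[b],
                                   edge_trim = edge_trim)
          mat[tr, ] <- vectorize_upper(C)
        }
        blocks[[length(blocks) + 1L]] <- mat
        index[[length(index) + 1L]] <-
          dplyr::mutate(pidx[, c("ch1", "ch2")],
                        measure = ms, band = b, window = m)
      }
    }
  }
  values <- do.call(cbind, blocks)
  index <- dplyr::bind_rows(index)
  index <- dplyr::mutate(index, feature = dplyr::row_number(),
                         .before = 1L)
  structure(list(values = values, index = index, labels = eeg$labels,
                 subject_id = eeg$subject_id, sigmas = sigmas,
                 grid = grid, channel_names = eeg$channel_names),
            class = "fc_features")
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("<fc_features> %d trials x %d features (%s; bands %s; %d windows)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$index$measure), collapse = "+"),
              paste(unique(x$index$band), collapse = ","),
              x$grid$n_windows))
  invisible(x)
}

#' @export
as_tibble.fc_features <- function(x, ...) {
  vals <- tibble::as_tibble(x$values, .name_repair = ~ paste0("f", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(trial = seq_len(nrow(x$values)),
                                  label = x$labels,
                                  subject = x$subject_id), vals)
}
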