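#' Write a feature object to delimited text
#'
#' Persists the values matrix as CSV (one row per trial, plus `trial` and
#' `label` columns when labels exist) and the feature index as a sibling
#' `<stem>_index.csv`.
#'
#' @param x an `fc_features`, `audio_features`, or plain matrix.
#' @param path output CSV path; the index goes to
#'   `sub("\\.csv$", "_index.csv", path)`.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  vals <- if (is.list(x) && !is.null(x$values)) x$values else as.matrix(x)
  df <- as.data.frame(vals)
  names(df) <- paste0("f", seq_len(ncol(df)))
  if (is.list(x) && !is.null(x$labels)) {
    df <- cbind(trial = seq_len(nrow(df)), label = x$labels, df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (is.list(x) && !is.null(x$index)) {
    utils::write.csv(as.data.frame(x$index),
                     sub("\\.csv$", "_index.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path CSV path.
#' @return List with `values` matrix, `labels` (or NULL), and `index`
#'   tibble if the sibling index file exists.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df$label)
    df <- df[, setdiff(names(df), c("trial", "label")), drop = FALSE]
  }
  idx_path <- sub("\\.csv$", "_index.csv", path)
  index <- if (file.exists(idx_path)) tibble::as_tibble(utils::read.csv(idx_path)) else NULL
  list(values = as.matrix(df), labels = labels, index = index)
}

#' Read epoched EEG from delimited text
#'
#' Expects a long CSV with columns `trial`, `channel`, and the samples
#' `s1...sN` (one row per trial/channel), plus optional `label` per trial.
#'
#' @param path CSV path.
#' @param fs sampling rate of the stored samples.
#' @param subject_id identifier.
#' @return An [eeg_epochs()] object.
#' @export
read_eeg_csv <- function(path, fs, subject_id = "S01") {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("trial", "channel") %in% names(df)))
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  trials <- sort(unique(df$trial))
  chans <- unique(df$channel)
  arr <- array(0, c(length(trials), length(chans), length(scols)))
  labels <- rep("unlabeled", length(trials))
  for (r in seq_len(nrow(df))) {
    ti <- match(df$trial[r], trials)
    ci <- match(df$channel[r], chans)
    arr[ti, ci, ] <- as.numeric(df[r, scols])
    if ("label" %in% names(df)) labels[ti] <- as.character(df$label[r])
  }
  eeg_epochs(arr, fs, chans, labels, subject_id)
}
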