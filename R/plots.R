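#' @export
autoplot.sweep_result <- function(object, ...) {
  axis <- attr(object, "axis") %||% "setting"
  long <- tidyr::pivot_longer(object, c("r_squared_mean", "gamma"),
                              names_to = "metric", values_to = "value")
  long$setting <- factor(long$setting, levels = unique(object$setting))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$setting, y = .data$value,
                                     group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = axis, y = NULL,
                  title = sprintf("LCA sweep over %s", axis)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lca_fit <- function(object, type = c("electrodes", "variates"), ...) {
  type <- match.arg(type)
  if (type == "electrodes") {
    if (is.null(object$electrode_relevance)) {
      stop_param("No electrode relevance on this fit (no feature index).")
    }
    df <- object$electrode_relevance
    df$electrode <- factor(df$electrode, levels = rev(df$electrode))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$relevance, y = .data$electrode)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "normalized relevance", y = NULL,
                      title = "Electrode relevance (CKA back-projection)") +
        ggplot2::theme_minimal()
    )
  }
  df <- object$variates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "EEG canonical variate", y = "audio canonical variate",
                  title = sprintf("Canonical variates (r = %.3f)", object$r)) +
    ggplot2::theme_minimal()
}

#' Plot a set of envelopes
#'
#' @param envelopes n x L matrix of envelopes (rows), e.g. from
#'   [sonify()].
#' @param labels optional per-row labels for colouring.
#' @param fs envelope sampling rate (64 Hz).
#' @return A ggplot object.
#' @export
plot_envelopes <- function(envelopes, labels = NULL, fs = 64) {
  M <- as.matrix(envelopes)
  df <- tibble::tibble(
    trial = rep(seq_len(nrow(M)), each = ncol(M)),
    time = rep((seq_len(ncol(M)) - 1) / fs, nrow(M)),
    value = as.numeric(t(M)),
    label = if (is.null(labels)) "all" else rep(labels, each = ncol(M))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$trial,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time [s]", y = "envelope",
                  title = "Acoustic envelopes") +
    ggplot2::theme_minimal()
}
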