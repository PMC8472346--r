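#' Plot an IMF decomposition
#'
#' One facet per component (IMFs in extraction order, residual last),
#' sharing the time axis.
#'
#' @param object An `imf_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imf_set <- function(object, ...) {
  df <- tidy.imf_set(object)
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a marginal Hilbert spectrum
#'
#' Energy (a.u.) against frequency (Hz), with the dominant frequency marked.
#'
#' @param object A `hilbert_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hilbert_spectrum <- function(object, ...) {
  df <- tidy.hilbert_spectrum(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "energy (a.u.)") +
    ggplot2::theme_minimal()
  if (sum(df$energy) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = dominant_frequency(object),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot decoding time courses
#'
#' Thin per-participant AUC traces with the group mean overlaid and the
#' chance level at 0.5.
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy.decoding_result(object)
  gm <- dplyr::summarise(dplyr::group_by(df, .data$time_ms),
                         auc = mean(.data$auc), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$auc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_line(data = gm, linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "AUC",
                  title = sprintf("%s vs %s [%s]", object$pair[1],
                                  object$pair[2], object$feature)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster permutation result
#'
#' Group t series with the cluster-forming threshold and significant
#' clusters shaded.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(time_ms = object$times_ms, t = object$t_series)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$t)) +
    ggplot2::geom_hline(yintercept = object$params$t_thresh,
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "t") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "#b2182b")
  }
  p
}
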