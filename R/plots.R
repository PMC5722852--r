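#' Plot a time-frequency energy map
#'
#' @param object An `eeg_tfmap`.
#' @param ... Unused.
#' @return A ggplot raster of wavelet energy over time and frequency, with
#'   a dashed line at stimulus onset.
#' @export
autoplot.eeg_tfmap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(E(f, t))) +
    ggplot2::labs(x = "Time from onset (s)", y = "Frequency (Hz)",
                  title = sprintf("Wavelet energy (%s, n = %d)",
                                  object$group, object$n_averaged)) +
    ggplot2::theme_minimal()
}

#' Plot class-difference traces per channel
#'
#' @param object An `erp_diff`.
#' @param channels Channels to show (default O1, O2, Pz, Fz).
#' @param ... Unused.
#' @return A ggplot of `Delta_p(t)` faceted by channel, with the
#'   0.2-0.4 s and 0.6-0.8 s component windows shaded.
#' @export
autoplot.erp_diff <- function(object, channels = c("O1", "O2", "Pz", "Fz"),
                              ...) {
  df <- dplyr::filter(tidy(object), .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$delta)) +
    ggplot2::annotate("rect", xmin = 0.2, xmax = 0.4, ymin = -Inf,
                      ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = 0.6, xmax = 0.8, ymin = -Inf,
                      ymax = Inf, alpha = 0.12, fill = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "Time from onset (s)",
                  y = expression(Delta[p](t) ~ "(" * mu * "V)")) +
    ggplot2::theme_minimal()
}

#' Plot the cross-subject transfer matrix
#'
#' @param object An `xsub_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map of accuracy for every trainer/test pair.
#' @export
autoplot.xsub_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$h, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$rho)),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(rho ~ "(%)"),
                                  limits = c(0, 100)) +
    ggplot2::labs(x = "Test subject r", y = "Training subject h") +
    ggplot2::theme_minimal()
}

#' Plot restart loss traces of a training run
#'
#' @param object An `mlp_training`.
#' @param ... Unused.
#' @return A ggplot of the accepted-step loss trace of every restart (log
#'   scale), best restart highlighted.
#' @export
autoplot.mlp_training <- function(object, ...) {
  df <- purrr::imap_dfr(object$restarts$mu_trace, function(tr, i) {
    tibble(restart = i, step = seq_along(tr) - 1, mu = tr)
  })
  df$best <- df$restart == object$best_index
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$mu,
                                   group = .data$restart,
                                   colour = .data$best)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Accepted LM step", y = expression(mu)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
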