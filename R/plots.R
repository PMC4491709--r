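# shared x-axis: substructures labelled "q.s", grouped by class
spectrum_axis <- function(df) {
  df$entry <- factor(paste0(df$class_id, ".", df$member_id),
                     levels = paste0(build_catalog()$class_id, ".",
                                     build_catalog()$member_id))
  df
}

#' Plot an ordered motif spectrum
#'
#' Appearance numbers per substructure on a log scale (counts span orders of
#' magnitude); zero counts cannot be drawn on the log axis and are dropped.
#'
#' @param object A `motif_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_spectrum
#' @export
autoplot.motif_spectrum <- function(object, ...) {
  df <- spectrum_axis(tibble::as_tibble(object))
  df <- df[df$eta > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entry, y = .data$eta,
                                   colour = factor(.data$class_id))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "substructure (class.member)",
                  y = expression(eta[(q * "," * s)]),
                  colour = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot an ensemble's mean motif spectrum
#'
#' Ensemble means with +/- one standard deviation, log scale; entries never
#' observed are dropped.
#'
#' @param object A `motif_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_ensemble
#' @export
autoplot.motif_ensemble <- function(object, ...) {
  df <- spectrum_axis(object$summary)
  df <- df[df$mean > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entry, y = .data$mean,
                                   colour = factor(.data$class_id))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean - .data$sd, .Machine$double.xmin),
      ymax = .data$mean + .data$sd
    ), fatten = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "substructure (class.member)",
                  y = expression(bar(eta)[(q * "," * s)]),
                  colour = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a Z-score significance profile
#'
#' @param object A `z_profile`.
#' @param ... Unused.
#' @return A ggplot (degenerate entries dropped).
#' @method autoplot z_profile
#' @export
autoplot.z_profile <- function(object, ...) {
  df <- spectrum_axis(tibble::as_tibble(object))
  df <- df[!df$degenerate, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entry, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$entry, yend = 0),
                          colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$class_id)),
                        size = 2) +
    ggplot2::labs(x = "substructure (class.member)",
                  y = expression(Z[(q * "," * s)]), colour = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
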