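#' Plot a psychometric fit
#'
#' Observed proportion correct per delta-S level (point size ~ trials) with
#' the fitted sigmoid and the 0.5-probability threshold marked.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  agg <- object$data
  xmax <- max(agg$delta_s) * 1.05
  curve <- tibble::tibble(delta_s = seq(0, xmax, length.out = 200))
  curve$p <- psy_curve(curve$delta_s, object$m, object$s, object$gamma,
                       object$lapse, object$family)
  gg <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$delta_s)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_correct / .data$n_trials,
                                     size = .data$n_trials), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = expression(Delta * S), y = "P(correct)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    gg <- gg +
      ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 3)
  }
  gg
}

#' Plot spectra
#'
#' Overlay of one or more spectra (e.g. LED channels, receptor sensitivities).
#'
#' @param spectra Named list of spectrum tibbles, or a single spectrum.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  if (is.data.frame(spectra)) spectra <- list(spectrum = spectra)
  df <- purrr::imap_dfr(spectra, ~ dplyr::mutate(.x, curve = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot colour-line loci in the chromaticity planes
#'
#' Projections of target loci onto the xy (double-cone) and xz (UV) planes of
#' the noise-corrected space, with the achromatic point at the origin and
#' greys overlaid when given.
#'
#' @param targets Target tibble with `label`, `x`, `y`, `z` columns
#'   (e.g. from [build_colour_line()] or [score_stimuli()]).
#' @param greys Optional grey-set tibble from [select_grey_set()].
#' @return A ggplot.
#' @export
plot_colour_space <- function(targets, greys = NULL) {
  long <- dplyr::bind_rows(
    dplyr::transmute(targets, .data$label, h = .data$x, v = .data$y, plane = "x-y"),
    dplyr::transmute(targets, .data$label, h = .data$x, v = .data$z, plane = "x-z")
  )
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v,
                                           colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = tibble::tibble(h = 0, v = 0, plane = c("x-y", "x-z")),
                        inherit.aes = FALSE, ggplot2::aes(x = .data$h, y = .data$v),
                        shape = 3, size = 3) +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "colour set") +
    ggplot2::theme_minimal()
  if (!is.null(greys)) {
    glong <- dplyr::bind_rows(
      dplyr::transmute(greys, h = .data$x, v = .data$y, plane = "x-y"),
      dplyr::transmute(greys, h = .data$x, v = .data$z, plane = "x-z")
    )
    gg <- gg + ggplot2::geom_point(data = glong, inherit.aes = FALSE,
                                   ggplot2::aes(x = .data$h, y = .data$v),
                                   colour = "grey50", shape = 1)
  }
  gg
}

#' Plot per-set thresholds
#'
#' Mean threshold per colour set with standard-error bars, coloured by the
#' sign of UV contrast, against the nominal 1 delta-S line.
#'
#' @param set_summary Tibble from [summarise_thresholds()].
#' @return A ggplot.
#' @export
plot_thresholds <- function(set_summary) {
  df <- dplyr::arrange(set_summary, .data$mean_threshold)
  df$colour_set <- factor(df$colour_set, levels = df$colour_set)
  aes_col <- if ("uv_sign" %in% names(df)) {
    ggplot2::aes(x = .data$colour_set, y = .data$mean_threshold,
                 fill = .data$uv_sign)
  } else {
    ggplot2::aes(x = .data$colour_set, y = .data$mean_threshold)
  }
  ggplot2::ggplot(df, aes_col) +
    ggplot2::geom_col(alpha = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_threshold - .data$sem,
                   ymax = .data$mean_threshold + .data$sem),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression("threshold (" * Delta * S * ")"),
                  fill = "UV contrast") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
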