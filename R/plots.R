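#' Plot calibration points and fitted curves
#'
#' Reproduces the standard matrix-comparison calibration figure: response
#' against level, one colour per matrix, with the fitted lines overlaid.
#'
#' @param points Response points from [build_response_points()], usually
#'   filtered to one compound.
#' @param curves Optional matching curve tibble from [fit_curves()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(points, curves = NULL) {
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data$level, y = .data$response,
                                    colour = .data$matrix)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "Level (ng/mL)", y = "Response",
                  colour = "Matrix") +
    ggplot2::theme_minimal()
  if (!is.null(curves)) {
    p <- p + ggplot2::geom_abline(
      data = curves,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$matrix)
    )
  }
  p
}

#' Box plot of matrix effects per soil
#'
#' External- vs internal-mode matrix-effect distributions per matrix, the
#' standard way to show how IL-IS normalization collapses matrix
#' enhancement.
#'
#' @param me A tibble from [matrix_effects()] (any mix of modes).
#' @return A ggplot object.
#' @export
plot_matrix_effects <- function(me) {
  ggplot2::ggplot(me, ggplot2::aes(x = .data$matrix, y = .data$me_pct,
                                   fill = .data$mode)) +
    ggplot2::geom_hline(yintercept = c(-20, 20), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Soil matrix", y = "Matrix effect (%)",
                  fill = "Calibration mode") +
    ggplot2::theme_minimal()
}

#' Occurrence bar chart for a monitoring batch
#'
#' Detection counts per compound with median and maximum reported
#' concentrations on a secondary layer, compounds ordered by frequency.
#'
#' @param occurrence Output of [summarize_occurrence()].
#' @param min_detects Hide compounds with fewer detects than this.
#' @return A ggplot object.
#' @export
plot_occurrence <- function(occurrence, min_detects = 1) {
  dat <- occurrence %>%
    filter(.data$n_detects >= min_detects) %>%
    arrange(dplyr::desc(.data$n_detects)) %>%
    mutate(compound = factor(.data$compound, levels = .data$compound))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$compound)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_detects), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_conc), colour = "red",
                        shape = 1, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_conc), colour = "black",
                        shape = 2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Detections (bars) / conc. ng/g (points)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
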