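#' EdU x DNA gating scatter plot
#'
#' The bivariate cytometry view: log EdU against log DNA content, one
#' point per nucleus coloured by assigned phase, with the fitted EdU
#' threshold and 2N/4N peaks drawn for each sample.
#'
#' @param labeled Output of [gate_cells()] (gating models read from the
#'   attribute if present).
#' @param dna,edu Intensity column names.
#' @return A ggplot object (facetted by sample).
#' @export
plot_gating <- function(labeled, dna = "dna_total", edu = "edu_total") {
  p <- ggplot2::ggplot(labeled,
                       ggplot2::aes(.data[[dna]], .data[[edu]],
                                    colour = .data$phase)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "DNA content (total intensity)",
                  y = "EdU (total intensity)", colour = "Phase") +
    ggplot2::theme_minimal()
  models <- attr(labeled, "gating_models")
  if (!is.null(models)) {
    lines <- purrr::map_dfr(models, glance_gating_row)
    p <- p +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$edu_threshold),
                          linetype = "dashed", colour = "grey30") +
      ggplot2::geom_vline(data = lines,
                          ggplot2::aes(xintercept = .data$g1_peak),
                          linetype = "dotted", colour = "grey30") +
      ggplot2::geom_vline(data = lines,
                          ggplot2::aes(xintercept = .data$g2_peak),
                          linetype = "dotted", colour = "grey30")
  }
  p
}

#' Per-phase marker density overlay
#'
#' @param densities Output of [marker_density_by_phase()].
#' @return A ggplot object: density vs intensity (log x), coloured by
#'   sample, facetted by phase.
#' @export
plot_marker_density <- function(densities) {
  ggplot2::ggplot(densities,
                  ggplot2::aes(.data$intensity, .data$density,
                               colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = paste0(densities$marker[1], " (total intensity)"),
                  y = "Density (per unit log intensity)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Volcano plot for a differential-viability screen
#'
#' @param result A [moderated_t_test()] result.
#' @param q_cutoff Highlight compounds with `q_value` below this.
#' @return A ggplot object: log2 viability difference vs -log10 p.
#' @export
plot_volcano <- function(result, q_cutoff = 0.05) {
  df <- tidy(result)
  df$hit <- df$q_value < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(.data$delta, .data$neg_log10_p,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 relative viability difference (arm2 - arm1)",
                  y = "-log10 p", colour = paste0("q < ", q_cutoff)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_volcano
#' @param object A `cc_screen_result`.
#' @param ... Passed to [plot_volcano()].
#' @export
autoplot.cc_screen_result <- function(object, ...) {
  plot_volcano(object, ...)
}
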