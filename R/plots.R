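# Plotting: core maps, group comparisons, survival curves.  All plots are
# ggplot2 objects the caller can restyle.

#' Map of one core: tumor clusters and compartment-banded immune cells
#'
#' @param zoned Output of [zone_cells()] for one core.
#' @param clusters The matching `tumor_clusters`.
#' @return A ggplot: cluster outlines with immune cells colored by
#'   compartment and shaped by phenotype.
#' @export
plot_core_zones <- function(zoned, clusters) {
  polys <- cluster_polygons(clusters)
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(.data$x_um, .data$y_um, group = .data$ring),
      fill = "grey85", colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = zoned,
      ggplot2::aes(.data$x_um, .data$y_um, colour = .data$zone,
                   shape = .data$cell_class),
      size = 1
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "compartment", shape = "phenotype") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_cohort Plot group means with SD error bars per
#'   phenotype and compartment, annotated with Wilcoxon p-values.
#' @param object A `cohort_comparison`.
#' @param ... Ignored.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  d <- object$densities |>
    tidyr::pivot_longer(cols = c("mean_1", "mean_2"),
                        names_to = "which", values_to = "mean") |>
    mutate(
      group = ifelse(.data$which == "mean_1", object$groups[1L],
                     object$groups[2L]),
      sd = ifelse(.data$which == "mean_1", .data$sd_1, .data$sd_2)
    )
  labs_p <- object$densities |>
    mutate(label = paste0("p = ", signif(.data$p_value, 2)))
  ggplot2::ggplot(d, ggplot2::aes(.data$zone, .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::geom_text(
      data = labs_p,
      ggplot2::aes(x = .data$zone, label = .data$label),
      y = Inf, vjust = 1.4, inherit.aes = FALSE, size = 3
    ) +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "density (cells/mm²)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn km_logrank Kaplan-Meier step curves with censoring marks.
#' @param object A `km_result`.
#' @param ... Ignored.
#' @export
autoplot.km_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = paste0("log-rank p = ",
                                     signif(object$p_value, 2))) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}
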