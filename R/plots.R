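#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of the element shape-quality distribution
#'
#' @param object A `mesh_quality` from [jacobian_quality()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mesh_quality <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$elements, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "shape quality Q (0 = regular tetrahedron)",
                  y = "elements",
                  title = "Element quality distribution") +
    ggplot2::theme_minimal()
}

#' Von Mises stress distribution of a solved phase by region group
#'
#' Empirical cumulative distributions of the per-element von Mises stress
#' for the enamel, dentin and restoration groups.
#'
#' @param object An `fea_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fea_solution <- function(object, ...) {
  df <- tidy.fea_solution(object)
  df$group <- NA_character_
  for (g in names(REGION_GROUPS))
    df$group[df$region %in% REGION_GROUPS[[g]]] <- g
  df <- df[!is.na(df$group), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$von_mises,
                                   colour = .data$group)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "von Mises stress (MPa)", y = "ECDF",
                  title = paste("Stress distribution -", object$phase)) +
    ggplot2::theme_minimal()
}

#' Bar chart of region-group maxima across scenarios and phases
#'
#' Mirrors the study's summary figure: maximum von Mises stress (or
#' displacement) per region group, faceted by phase, one bar per scenario.
#'
#' @param object A `study_report`.
#' @param metric `"max_vm"` (MPa) or `"max_displacement"` (mm).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, metric = c("max_vm",
                                                     "max_displacement"),
                                  ...) {
  metric <- match.arg(metric)
  lab <- if (metric == "max_vm") "max von Mises stress (MPa)"
         else "max displacement (mm)"
  ggplot2::ggplot(object$stats,
                  ggplot2::aes(x = .data$group, y = .data[[metric]],
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = NULL, y = lab,
                  title = "Region-group maxima by scenario") +
    ggplot2::theme_minimal()
}
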