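#' Paired roadside-vs-interior comparison plot
#'
#' One panel per beta metric: per-plot mean beta diversity by category, with
#' a line joining the two plots of each site (the paired design made
#' visible). A downward slope from interior to roadside indicates
#' homogenization.
#'
#' @param report A [run_study()] result.
#' @param metrics Which metrics to show; default all.
#' @return A ggplot object.
#' @export
plot_comparison <- function(report, metrics = NULL) {
  stopifnot(inherits(report, "study_report"))
  pm <- report$plot_means
  if (!is.null(metrics)) pm <- pm[pm$metric %in% metrics, ]
  pm$category <- factor(pm$category, levels = c("interior", "roadside"))
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$site_id),
                       alpha = 0.35, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                        show.legend = FALSE, size = 1.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "black") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-plot mean beta diversity") +
    ggplot2::theme_minimal()
}

#' Heatmap of between-facet Mantel correlations
#'
#' @param report A [run_study()] result.
#' @param category Which category's tests to show (default `"interior"`;
#'   use `"pooled"` if the report was run pooled).
#' @return A ggplot object.
#' @export
plot_mantel <- function(report, category = "interior") {
  stopifnot(inherits(report, "study_report"))
  mt <- report$mantel[report$mantel$category == category, ]
  if (!nrow(mt)) abort(paste0("no Mantel results for category '", category, "'"))
  mt$pair <- paste(mt$facet_1, "vs", mt$facet_2)
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$component, y = .data$pair,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r, ifelse(.data$p.value < 0.01, "**",
                                                ifelse(.data$p.value < 0.05, "*", "")))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Mantel r",
                  title = paste0("Between-facet correlations (", category, ")")) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_comparison autoplot method for study reports.
#' @param object,... Passed through to [plot_comparison()].
#' @export
#' @method autoplot study_report
autoplot.study_report <- function(object, ...) plot_comparison(object, ...)

#' Heatmap of one beta component matrix
#'
#' @param object A [beta_matrix()] result.
#' @param component Which component to draw (default `"beta_total"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot facet_beta
autoplot.facet_beta <- function(object, component = "beta_total", ...) {
  df <- tidy.facet_beta(object)
  if (!component %in% names(df)) abort(paste0("unknown component '", component, "'"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plot_i, y = .data$plot_j,
                                   fill = .data[[component]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(object$facet, " ", component),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
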