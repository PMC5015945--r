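#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a flag proportion against conservation depth
#'
#' Bar chart of the per-depth-bin percentage produced by
#' [depth_stratified_proportions()] (e.g. stress-responsiveness by
#' conservation depth).
#'
#' @param tab output of [depth_stratified_proportions()].
#' @param ylab y-axis label.
#' @return a ggplot.
#' @export
plot_depth_proportions <- function(tab, ylab = "% of loci") {
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$depth_age),
                                    y = .data$prop_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_flag), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "conservation depth (node age, Myr)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot per-species loss or decay proportions with groupings
#'
#' @param gs output of [group_species()].
#' @param metric label for the y axis.
#' @return a ggplot.
#' @export
plot_species_groups <- function(gs, metric = "lost") {
  d <- gs$species
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$species,
                                                     .data$prop),
                                  y = 100 * .data$prop,
                                  fill = factor(.data$group))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = paste0("% of loci ", metric),
                  fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot duplication events along the backbone
#'
#' @param dup_summary output of [summarize_duplications()].
#' @return a ggplot.
#' @export
plot_duplication_timing <- function(dup_summary) {
  d <- dup_summary$per_node
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(factor(.data$age),
                                                     -.data$age),
                                  y = .data$n_dup_events)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_families), vjust = -0.4,
                       size = 3, color = "purple") +
    ggplot2::labs(x = "backbone node age (Myr)",
                  y = "duplication events") +
    ggplot2::theme_minimal()
}

#' @rdname expression_depth_correlation
#' @param object a `linc_depth_fit`.
#' @export
autoplot.linc_depth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$depth_age,
                                            y = .data$log_fpkm)) +
    ggplot2::geom_jitter(width = 1, alpha = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = "conservation depth (Myr)",
                  y = "log10(mean FPKM + 0.01)",
                  subtitle = sprintf("r = %.3f, p = %.2g", object$r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
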