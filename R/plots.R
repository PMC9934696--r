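#' Scatter plot of score vs phenotype with deviators highlighted
#'
#' The standard diagnostic view: standardized polygenic score against
#' standardized phenotype, concordant/indeterminate individuals in grey-black
#' and flagged deviators coloured by direction.
#'
#' @param classification A `pgs_classification` tibble (single method, or use
#'   `facet = TRUE` for several).
#' @param data The scored cohort the classification was computed from
#'   (columns `id`, `ps_std`, `pheno_std`).
#' @param facet Facet by method?
#' @return A ggplot object.
#' @export
plot_deviators <- function(classification, data, facet = length(unique(classification$method)) > 1) {
  check_scored(data)
  df <- dplyr::left_join(classification,
                         dplyr::select(data, "id", "ps_std", "pheno_std"),
                         by = "id")
  df$flagged <- df$label %in% c("lower", "higher")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ps_std, y = .data$pheno_std)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !.data$flagged),
                        colour = "grey30", size = 0.4, alpha = 0.4) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$flagged),
                        ggplot2::aes(colour = .data$label), size = 1.2) +
    ggplot2::scale_colour_manual(values = c(lower = "#D55E00", higher = "#0072B2"),
                                 name = "deviation") +
    ggplot2::labs(x = "standardized polygenic score",
                  y = "standardized phenotype") +
    ggplot2::theme_minimal()
  if (facet) p <- p + ggplot2::facet_wrap(~method)
  p
}

#' @rdname plot_deviators
#' @param object,x A `pgs_classification` tibble.
#' @param ... Passed on to [plot_deviators()] (must include `data`).
#' @export
autoplot.pgs_classification <- function(object, ...) {
  plot_deviators(object, ...)
}

#' Forest-style plot of an enrichment panel
#'
#' Point estimates and confidence intervals for each group x trait test, on a
#' log scale for odds ratios.
#'
#' @param panel An `enrichment_panel` tibble from [run_enrichment_panel()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(panel) {
  df <- dplyr::filter(panel, !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$trait,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "estimate (OR or SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_enrichment
#' @param object An `enrichment_panel` tibble.
#' @param ... Unused.
#' @export
autoplot.enrichment_panel <- function(object, ...) {
  plot_enrichment(object)
}
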