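# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accessibility surface
#'
#' Point map of township accessibility when coordinates are available,
#' otherwise a histogram of the accessibility distribution.
#'
#' @param object An [compute_accessibility()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fca_accessibility
#' @export
autoplot.fca_accessibility <- function(object, ...) {
  tab <- object$townships
  if (!anyNA(tab$x_km) && !anyNA(tab$y_km)) {
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$x_km, y = .data$y_km,
                                      colour = .data$A,
                                      size = .data$population)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_colour_viridis_c(trans = "sqrt") +
      ggplot2::coord_equal() +
      ggplot2::labs(title = paste("Accessibility,", object$scenario$name),
                    x = "x (km)", y = "y (km)", colour = "A",
                    size = "population") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$A)) +
      ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                              colour = "white") +
      ggplot2::labs(title = paste("Accessibility,", object$scenario$name),
                    x = "A", y = "townships") +
      ggplot2::theme_minimal()
  }
}

#' Plot four-class accessibility population shares
#'
#' Stacked bars of the population share per accessibility class, per city.
#'
#' @param object An [classify_accessibility()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fca_classification
#' @export
autoplot.fca_classification <- function(object, ...) {
  shares <- object$shares
  shares$class <- factor(shares$class, levels = rev(.access_classes))
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$region, y = .data$share,
                                       fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = 1) +
    ggplot2::labs(x = NULL, y = "population share", fill = "class",
                  title = paste0("Accessibility classes (",
                                 object$method, " breaks)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-tier contribution rates
#'
#' Stacked bars of the primary / county / municipal contribution shares per
#' region.
#'
#' @param object An [contribution_rates()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fca_contribution
#' @export
autoplot.fca_contribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object$regions,
                              cols = dplyr::starts_with("share_"),
                              names_to = "tier", names_prefix = "share_",
                              values_to = "share")
  long$tier <- factor(long$tier, levels = c("municipal", "county", "primary"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$share,
                                     fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution to accessibility",
                  fill = "tier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Compare mean accessibility across scenarios
#'
#' Bar chart of mean township accessibility with a population-sd ribbon,
#' one bar per scenario.
#'
#' @param results Named list of [compute_accessibility()] results.
#' @return A ggplot object.
#' @export
plot_scenario_comparison <- function(results) {
  tab <- summarize_scenarios(results)
  tab$scenario <- factor(tab$scenario, levels = tab$scenario)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$scenario, y = .data$mean_A)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_A - .data$sd_A,
                                                    0),
                                        ymax = .data$mean_A + .data$sd_A),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean accessibility") +
    ggplot2::theme_minimal()
}
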