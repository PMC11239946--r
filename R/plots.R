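#' Plot per-region deposit density
#'
#' Bar chart of density mean with an SD error bar per region, the standard
#' presentation for regional burden tables.
#'
#' @param object A tibble from [region_summary()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.region_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$roi_name,
                                       y = .data$density_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$density_mean - .data$density_sd),
      ymax = .data$density_mean + .data$density_sd), width = 0.25) +
    ggplot2::labs(x = NULL, y = expression(Deposits / mm^2)) +
    ggplot2::theme_minimal()
}

#' Plot the two-population diameter split
#'
#' Log-scale histogram of equivalent diameters with the oligomer/plaque
#' threshold marked.
#'
#' @param object A `population_split`.
#' @param diameters_um The diameters the split was fitted to.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.population_split <- function(object, diameters_um, bins = 40, ...) {
  df <- tibble(diameter = diameters_um, class = object$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter,
                                   fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$threshold_um,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Equivalent diameter (µm)", y = "Objects",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a clone ranking
#'
#' Mean positive-pixel count with SD error bars, best clone first.
#'
#' @param object A `clone_ranking`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.clone_ranking <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      clone_id = factor(.data$clone_id,
                                        levels = .data$clone_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clone_id,
                                   y = .data$mean_count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_count - .data$sd_count),
      ymax = .data$mean_count + .data$sd_count), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Positive pixels (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot deposit-nucleus association fractions
#'
#' @param object An `association_summary`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.association_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class,
                                       y = .data$fraction_perinuclear)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Fraction perinuclear") +
    ggplot2::theme_minimal()
}
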