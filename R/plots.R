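# ggplot2 views of the main result types.

#' Plot observed vs null nearest-gene distance densities
#'
#' Densities of log10(distance + 1) for the observed intergenic elements
#' (solid) and the pooled random placements (dashed), the standard way to
#' show whether elements sit closer to genes than chance — bimodal
#' observed curves indicate two populations with different gene
#' proximity.
#'
#' @param profile A [distance_null()] result.
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  d <- distance_density(profile)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_distance,
                                  y = .data$density,
                                  colour = .data$source,
                                  linetype = .data$source)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(observed = "#2166ac",
                                            null = "#b2182b")) +
    ggplot2::labs(
      x = "log10(distance to nearest gene + 1)", y = "density",
      subtitle = sprintf("K-S D = %.3f, p = %.3g (%s to genes than null)",
                         profile$statistic, profile$p_value,
                         profile$direction)) +
    ggplot2::theme_minimal()
}

#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, ...) {
  plot_distance_profile(object)
}

#' Plot along-chromosome binned profiles
#'
#' Percent of each track's features per bin, faceted by chromosome — the
#' histogram view that shows clustering of elements at chromosome ends or
#' interiors, and lets element and gene tracks be compared by eye.
#'
#' @param profile A [bin_profile()] result.
#' @param tracks Optional subset of tracks to show.
#' @return A ggplot object.
#' @export
plot_bin_profile <- function(profile, tracks = NULL) {
  d <- as_tibble(profile)
  if (!is.null(tracks)) d <- d[d$track %in% tracks, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$percent,
                                  fill = .data$track)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "chromosome bin", y = "% of track's features") +
    ggplot2::theme_minimal()
}

#' Plot a regression from the count table
#'
#' @param object A [linear_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lin_fit
#' @export
autoplot.lin_fit <- function(object, ...) {
  d <- tibble(x = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2166ac") +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("R² = %.3f, p = %.3g",
                                     object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
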