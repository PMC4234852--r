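#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_ribbon
#'   geom_col geom_point scale_fill_manual labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

spread_mod_colours <- c(U = "grey30", A = "forestgreen", M = "firebrick")

#' Plot a kymograph
#'
#' Position-by-time raster of modification states, with bound enzymes
#' overdrawn as points.
#'
#' @param object A [kymograph()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_kymograph
#' @export
autoplot.spread_kymograph <- function(object, ...) {
  occ_df <- dplyr::filter(object, .data$occ != "empty")
  ggplot(object, aes(x = .data$time, y = .data$position)) +
    geom_tile(aes(fill = .data$mod)) +
    geom_point(data = occ_df, aes(shape = .data$occ), size = 0.6,
               colour = "orange") +
    scale_fill_manual(values = spread_mod_colours) +
    labs(x = "time (s)", y = "nucleosome position", fill = "mark",
         shape = "enzyme") +
    theme_minimal()
}

#' Plot a positional profile
#'
#' Per-position steady-state probabilities of each mark and of enzyme
#' occupancy.
#'
#' @param object A [positional_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_profile
#' @export
autoplot.spread_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"position", names_to = "series",
                              values_to = "prob")
  ggplot(long, aes(x = .data$position, y = .data$prob,
                   colour = .data$series)) +
    geom_line() +
    labs(x = "nucleosome position", y = "time-weighted probability",
         colour = NULL) +
    theme_minimal()
}

#' Plot binned ensemble dynamics
#'
#' Median trace with interquartile and full-range ribbons.
#'
#' @param object A [binned_dynamics()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_dynamics
#' @export
autoplot.spread_dynamics <- function(object, ...) {
  ggplot(object, aes(x = .data$time)) +
    geom_ribbon(aes(ymin = .data$min, ymax = .data$max), fill = "orange",
                alpha = 0.25) +
    geom_ribbon(aes(ymin = .data$q25, ymax = .data$q75), fill = "orange",
                alpha = 0.5) +
    geom_line(aes(y = .data$median)) +
    labs(x = "time (s)", y = attr(object, "observable")) +
    theme_minimal()
}

#' Plot a total-count distribution
#'
#' @param object A [count_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_count_distribution
#' @export
autoplot.spread_count_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$count, y = .data$prob)) +
    geom_col(width = 0.9) +
    labs(x = paste0("total ", unique(object$species)),
         y = "time-weighted probability") +
    theme_minimal()
}

#' Plot boundary-statistic distributions
#'
#' Replicate distributions of total methylation minus total acetylation,
#' one panel per sampling window.
#'
#' @param object A [boundary_statistic()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_boundary
#' @export
autoplot.spread_boundary <- function(object, ...) {
  dist <- boundary_distribution(object)
  ggplot(dist, aes(x = .data$value, y = .data$prob)) +
    geom_col(width = 0.9) +
    facet_wrap(~window_start, labeller = ggplot2::label_both) +
    labs(x = "total M - total A", y = "probability") +
    theme_minimal()
}
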