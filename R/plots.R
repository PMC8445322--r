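#' Plot a normalized decay curve
#'
#' @param object A [decay_curve()].
#' @param window Optional fit window (minutes) to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_curve <- function(object, window = c(90, 360), ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    ggplot2::labs(
      x = "Time (min)",
      y = "Normalized EL GFP intensity",
      title = attr(object, "condition_label") %||% NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08,
                               fill = "#fdae61")
  }
  p
}

#' Plot simulated reporter pool trajectories
#'
#' @param object A `pool_sim` tibble from [simulate_pools()].
#' @param ... Unused.
#' @return A ggplot of every pool plus the observable endolysosomal signal
#'   over time.
#' @export
autoplot.pool_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t_min",
                              names_to = "pool", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$fraction,
                                     colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Fraction of initial EL reporter",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted kinetic model over its data
#'
#' @param object A `kinetics_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A ggplot overlaying the fitted observable on the measured curve.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.6,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#d7301f") +
    ggplot2::labs(x = "Time (min)", y = "Normalized EL GFP intensity") +
    ggplot2::theme_minimal()
}

#' Bar plot of the ILV fate partition
#'
#' @param object A `fate_breakdown` tibble from [retrofusion_lower_bound()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fate_breakdown <- function(object, ...) {
  long <- tibble(
    fate = c("secreted (of MVB pool)", "degraded (of ILV pool)",
             "retrofused (lower bound)", "inert remaining"),
    fraction = c(object$frac_secreted_of_mvb, object$frac_degraded_of_ilv,
                 object$frac_retrofused_of_ilv_lower_bound,
                 object$frac_inert_remaining)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fate, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fraction") +
    ggplot2::theme_minimal()
}
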