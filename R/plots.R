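#' Plot methods for simulated adjusting-energy experiments
#'
#' `autoplot()` on a condition or experiment draws the session-by-session
#' mean AE requirement (the titration trajectory). The `plot_*` helpers
#' mirror the standard summary figures: indifference points against the FR
#' requirement, IRE distributions against the AE requirement, and total
#' energy per reinforcement against the AE requirement.
#'
#' @param object,x An `"ae_condition"`, `"ae_experiment"` or
#'   `"ae_summaries"` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name ae_plots
NULL

#' @rdname ae_plots
#' @export
autoplot.ae_condition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$session_index,
                               y = .data$mean_ae_requirement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Session", y = "Mean AE requirement (J)",
                  title = object$condition_label) +
    ggplot2::theme_minimal()
}

#' @rdname ae_plots
#' @export
autoplot.ae_experiment <- function(object, ...) {
  df <- tidy(object)
  df$condition_label <- factor(df$condition_label,
                               levels = unique(df$condition_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_index,
                                   y = .data$mean_ae_requirement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~condition_label, scales = "free_x") +
    ggplot2::labs(x = "Session", y = "Mean AE requirement (J)") +
    ggplot2::theme_minimal()
}

summaries_of <- function(x) {
  if (inherits(x, "ae_summaries")) return(x$summaries)
  if (inherits(x, "ae_experiment") || is.list(x)) {
    return(condition_summaries(x)$summaries)
  }
  ae_abort("Expected an `ae_summaries` or `ae_experiment` object.",
           "aeforage_error_invalid_argument")
}

#' @rdname ae_plots
#' @export
plot_indifference <- function(x, ...) {
  s <- summaries_of(x)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$fr_requirement,
                                  y = .data$indifference_point)) +
    ggplot2::geom_path(linetype = "dashed", colour = "grey60",
                       arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$series), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(ascending = 1, descending = 16)) +
    ggplot2::labs(x = "FR requirement", y = "Indifference point (J)",
                  shape = "Series") +
    ggplot2::theme_minimal()
}

#' @rdname ae_plots
#' @export
plot_ire_distribution <- function(x, ...) {
  s <- summaries_of(x)
  pts <- tidyr::unnest(
    dplyr::select(s, "indifference_point", "ire_samples"),
    "ire_samples"
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$indifference_point,
                                    y = .data$ire_samples)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_point(data = s,
                        ggplot2::aes(y = .data$mean_ire),
                        shape = 1, size = 3) +
    ggplot2::labs(x = "AE requirement (indifference point, J)",
                  y = "IRE (J)") +
    ggplot2::theme_minimal()
}

#' @rdname ae_plots
#' @export
plot_e_per_rft <- function(x, ...) {
  s <- summaries_of(x)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$indifference_point,
                                  y = .data$e_per_rft)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$series), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(ascending = 1, descending = 16)) +
    ggplot2::labs(x = "AE requirement (indifference point, J)",
                  y = "Total energy per reinforcement (J)",
                  shape = "Series") +
    ggplot2::theme_minimal()
}
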