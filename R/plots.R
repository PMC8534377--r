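#' Plot multiscale curves
#'
#' ggplot2 views of the sweep outputs, each taking the corresponding tibble
#' first so they chain with the pipe: mean functional strength, Von Neumann
#' entropy (raw or normalised) and functional module counts against the
#' rescaled scale \eqn{\tau/\tau_d} on a log axis, and the empirical-vs-RWCM
#' entropy comparison with its gap.
#'
#' @param data the tibble produced by the matching curve function
#' @param normalised plot `entropy_norm` instead of `entropy`
#' @return a ggplot object
#' @export
plot_strength_curve <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$ratio, .data$mean_strength)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau / tau[d]),
                  y = expression(bar(k) / phi[0]),
                  title = "Mean functional strength across scales") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strength_curve
#' @export
plot_entropy_curve <- function(data, normalised = FALSE) {
  y <- if (normalised) "entropy_norm" else "entropy"
  ggplot2::ggplot(data, ggplot2::aes(.data$ratio, .data[[y]])) +
    ggplot2::geom_line(colour = "#d7301f") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau / tau[d]),
                  y = if (normalised) "S / log N" else "S (nats)",
                  title = "Von Neumann entropy across scales") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strength_curve
#' @export
plot_module_curve <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$ratio, .data$n_modules)) +
    ggplot2::geom_step(colour = "#238443") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau / tau[d]), y = "functional modules",
                  title = "Functional module count across scales") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strength_curve
#' @export
plot_entropy_gap <- function(data) {
  long <- tidyr::pivot_longer(
    dplyr::select(data, "ratio", real = "s_real", RWCM = "s_null_mean",
                  gap = "gap"),
    -"ratio", names_to = "series", values_to = "entropy"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$ratio, .data$entropy,
                                     colour = .data$series,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(real = "#d7301f",
                                            RWCM = "#2c7fb8",
                                            gap = "black")) +
    ggplot2::scale_linetype_manual(values = c(real = "solid",
                                              RWCM = "solid",
                                              gap = "dashed")) +
    ggplot2::labs(x = expression(tau / tau[d]), y = "S (nats)",
                  title = "Empirical vs RWCM entropy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Panel view of a sweep
#'
#' @param object a `funcstate_sweep`
#' @param ... unused
#' @return a ggplot object faceting strength, entropy and module count
#' @export
autoplot.funcstate_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object$strength, ratio = .data$ratio,
                     value = .data$mean_strength,
                     panel = "mean strength / phi0"),
    dplyr::transmute(object$entropy, ratio = .data$ratio,
                     value = .data$entropy, panel = "entropy S (nats)"),
    dplyr::transmute(object$modules, ratio = .data$ratio,
                     value = as.numeric(.data$n_modules),
                     panel = "functional modules")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$ratio, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression(tau / tau[d]), y = NULL) +
    ggplot2::theme_minimal()
}
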