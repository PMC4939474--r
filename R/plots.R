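#' Plot an FCS fit
#'
#' Data and fitted model curves on a log lag axis, one colour per curve.
#'
#' @param object An `fcs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcs_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, colour = .data$curve_id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  colour = NULL)
}

#' Plot the protonation rate law
#'
#' `k_prot` versus `[H+]` with the fitted line (slope `kappa_on`, intercept
#' `k_off`).
#'
#' @param object A `protonation_fit`.
#' @param points Optionally, the full point table (e.g. from
#'   [kprot_points()]) including points excluded by `h_max`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protonation_fit <- function(object, points = NULL, ...) {
  d <- if (is.null(points)) object$lm$model else tibble::as_tibble(points)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h_conc, y = .data$k_prot)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$kappa_on, intercept = object$k_off,
                         colour = "steelblue") +
    ggplot2::labs(x = expression("[H"^"+" * "] (M)"),
                  y = expression(k[prot] ~ (s^-1)))
}

#' Plot a buffer or disc-size sweep
#'
#' Overall `k_prot` and the pathway II / III partial on-rates against the
#' swept variable.
#'
#' @param object An `antenna_sweep` tibble from [sweep_buffer()] or
#'   [sweep_disc_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.antenna_sweep <- function(object, ...) {
  xvar <- if ("conc" %in% names(object)) "conc" else "diameter"
  xlab <- if (xvar == "conc") "buffer concentration (M)" else "disc diameter (nm)"
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c(xvar, "k_prot", "rate_II", "rate_III"))),
    -dplyr::all_of(xvar), names_to = "component", values_to = "rate")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$rate,
                                       colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = expression("rate" ~ (s^-1)), colour = NULL)
  if (xvar == "conc") p <- p + ggplot2::scale_x_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
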