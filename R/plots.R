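# ggplot2 display methods for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a photocurrent trace
#' @param object a `photocurrent_trace`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.photocurrent_trace <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
  lw <- attr(object, "light_window")
  if (!is.null(lw)) {
    p <- p + ggplot2::annotate("rect", xmin = lw[1], xmax = lw[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "darkgreen")
  }
  p
}

#' Plot occupancy trajectories per state
#' @param object an `occupancy_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.occupancy_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "state", values_to = "occupancy")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "occupancy")
}

#' Plot the EADS (or DADS) of a global fit
#' @param object a `sequential_fit`.
#' @param representation `"eads"` or `"dads"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sequential_fit <- function(object, representation = c("eads", "dads"), ...) {
  representation <- match.arg(representation)
  M <- object[[representation]]
  df <- tibble::tibble(
    axis = rep(object$axis_values, ncol(M)),
    spectrum = rep(paste0(toupper(representation), " ",
                          signif(object$lifetimes, 3), " s"),
                   each = nrow(M)),
    delta_A = as.vector(M))
  xlab <- if (object$axis_kind == "wavelength") "wavelength (nm)" else "wavenumber (1/cm)"
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$delta_A,
                                   colour = .data$spectrum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = expression(Delta * A))
}

#' Plot a titration fit
#' @param object a `boltzmann_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  grid <- seq(min(object$data$pH), max(object$data$pH), length.out = 200)
  h <- if (object$increasing) object$hill_slope else -object$hill_slope
  curve <- tibble::tibble(
    pH = grid,
    amplitude = boltzmann_curve(grid, object$plateaus[1], object$plateaus[2],
                                object$pK, h))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$pH, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$pK, linetype = 2) +
    ggplot2::labs(x = "pH", y = "amplitude")
}

#' Plot an action-spectrum fit
#' @param object a `weibull_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.weibull_fit <- function(object, ...) {
  wl <- object$data$wavelength_nm
  grid <- seq(min(wl), max(wl), length.out = 400)
  curve <- tibble::tibble(
    wavelength_nm = grid,
    response = object$amplitude * weibull_shape(grid, object$lambda0,
                                                object$beta, object$k))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$wavelength_nm, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$lambda_max_nm, linetype = 2) +
    ggplot2::labs(x = "wavelength (nm)", y = "normalized response")
}
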