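#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a velocity field into one row per plane pixel
#'
#' @param x A `velocity_field`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (pixel indices) and `velocity` (m/s).
#' @export
tidy.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                 y = rep(seq_len(d[2]), each = d[1]),
                 velocity = as.vector(x$values))
}

#' One-row summary of a velocity field
#'
#' @param x A `velocity_field`.
#' @param ... Unused.
#' @return Tibble with `method`, `f_c`, `mean`, `std`, `peak_correlation`,
#'   `n_pixels`.
#' @export
glance.velocity_field <- function(x, ...) {
  tibble::tibble(method = x$method, f_c = x$f_c, mean = x$mean, std = x$std,
                 peak_correlation = x$peak_correlation %||% NA_real_,
                 n_pixels = length(x$values))
}

#' @rdname tidy.velocity_field
#' @export
tidy.phase_field <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                 y = rep(seq_len(d[2]), each = d[1]),
                 phase = as.vector(x$values))
}

#' @rdname glance.velocity_field
#' @export
glance.phase_field <- function(x, ...) {
  tibble::tibble(method = "steady_state_phase", f_c = x$f_c, mean = x$mean,
                 std = x$std, peak_correlation = NA_real_,
                 n_pixels = length(x$values))
}

#' @rdname tidy.velocity_field
#' @export
tidy.phase_histogram <- function(x, ...) x$bins

#' @importFrom rlang %||%
NULL

#' Image of a per-pixel field over the measurement plane
#'
#' @param object A `velocity_field` or `phase_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$velocity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s velocity, %g kHz: %.0f ± %.0f m/s",
                                  object$method, object$f_c / 1e3,
                                  object$mean, object$std))
}

#' @rdname autoplot.velocity_field
#' @export
autoplot.phase_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(phi[s] ~ "(rad)"),
                                  limits = c(0, 2 * pi)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("steady-state phase, %g kHz: %.2f ± %.2f rad",
                                  object$f_c / 1e3, object$mean, object$std))
}

#' @rdname autoplot.velocity_field
#' @export
autoplot.phase_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lower + object$bin_width / 2,
                                   .data$probability)) +
    ggplot2::geom_col(width = object$bin_width) +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi)) +
    ggplot2::labs(x = "steady-state phase (rad)", y = "probability")
}
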