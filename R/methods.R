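#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname fit_power_law
#' @param x An `envelope_model`.
#' @param ... Unused.
#' @export
tidy.envelope_model <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(x$a, x$b, x$c),
    fixed = c(FALSE, FALSE, x$c_fixed)
  )
}

#' @rdname fit_power_law
#' @export
glance.envelope_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    nobs = if (is.null(x$data)) NA_integer_ else nrow(x$data),
    x_unit = x$x_unit
  )
}

#' Scatter of agreement versus percent error
#'
#' One point per simulated evaluator profile; marker shading encodes the
#' systematic error and marker size the random error, exposing the
#' worst-case envelope along the right edge of the cloud.
#'
#' @param object An `agreement_error_points` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_error_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_percent_error,
                                       y = .data$mean_alpha,
                                       colour = .data$mu,
                                       size = .data$sigma)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "systematic\nerror (mu)") +
    ggplot2::scale_size_continuous(name = "random\nerror (sigma)") +
    ggplot2::labs(x = "Mean percent error (%)", y = "Mean Krippendorff's alpha") +
    ggplot2::theme_minimal()
}

#' Envelope model curve over its fitting points
#'
#' @param object An `envelope_model`.
#' @param max_error_percent Right edge of the plotted error axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envelope_model <- function(object, max_error_percent = NULL, ...) {
  if (is.null(max_error_percent)) {
    max_error_percent <- if (!is.null(object$data)) 100 * max(object$data$x) else 40
  }
  grid <- tibble::tibble(err = seq(0, max_error_percent, length.out = 200))
  grid$alpha <- envelope_alpha(object, grid$err / 100)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$err, y = .data$alpha)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Worst-case percent error (%)", y = "Krippendorff's alpha") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(err = 100 * object$data$x, alpha = object$data$y),
      colour = "firebrick"
    )
  }
  p
}

#' Contour view of agreement and error over the error-parameter plane
#'
#' Two filled panels over the (mu, sigma) grid: mean alpha and mean percent
#' error. Agreement degrades with either error type; subset-total percent
#' error responds, on average, only to systematic error.
#'
#' @param points An `agreement_error_points` tibble on a complete grid.
#' @return A ggplot object faceted by quantity.
#' @export
plot_contours <- function(points) {
  long <- tidyr::pivot_longer(points, c("mean_alpha", "mean_percent_error"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("mean_alpha", "mean_percent_error"),
                          c("Krippendorff's alpha", "Percent error (%)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$sigma,
                                     fill = .data$value, z = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "Systematic error mu", y = "Random error sigma") +
    ggplot2::theme_minimal()
}

#' Serialize an envelope model to JSON
#'
#' @param model An `envelope_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "envelope_model"))
  jsonlite::write_json(
    list(a = model$a, b = model$b, c = model$c,
         r_squared = model$r_squared, x_unit = model$x_unit),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read an envelope model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return An `envelope_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- envelope_model(a = x$a, b = x$b, c = x$c,
                      r_squared = x$r_squared %||% NA_real_)
  m
}
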