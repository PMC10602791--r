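#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prediction set
#'
#' Predicted versus true hpf, one point per image, with the through-origin
#' least-squares line (solid) and, when a temperature column is present,
#' the rate expected from the temperature model (dashed).
#'
#' @param object A `prediction_set`.
#' @param x Abscissa column (default `true_hpf`).
#' @param model A [rate_model()] for the expected-rate guide line.
#' @param ... Unused.
#' @export
autoplot.prediction_set <- function(object, x = "true_hpf",
                                    model = rate_model(), ...) {
  fit <- fit_through_origin(object, x = x)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[x]], y = .data$predicted_hpf)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = fit$m, intercept = 0) +
    ggplot2::labs(x = if (x == "time_h") "time since fertilisation (h)" else
                    "true hpf",
                  y = "predicted hpf",
                  subtitle = sprintf("y = %.3f x, R² = %.3f",
                                     fit$m, fit$r_squared))
  if (x == "time_h" && length(unique(object$temperature_c)) == 1L) {
    p <- p + ggplot2::geom_abline(
      slope = relative_rate(object$temperature_c[1], model),
      intercept = 0, linetype = "dashed")
  }
  p
}

#' Plot two populations with their bootstrap slope cones
#'
#' The Fig-3-style view: each population's points, its through-origin fit,
#' and the [min, max] slope band drawn as a shaded cone through the origin.
#'
#' @param object A `population_analysis`.
#' @param names Labels for the two populations.
#' @param ... Unused.
#' @export
autoplot.population_analysis <- function(object,
                                         names = c("population A",
                                                   "population B"), ...) {
  xa <- object$fit_a$x; ya <- object$fit_a$y
  xb <- object$fit_b$x; yb <- object$fit_b$y
  pts <- dplyr::bind_rows(
    tibble::tibble(x = xa, y = ya, population = names[1]),
    tibble::tibble(x = xb, y = yb, population = names[2]))
  xmax <- max(pts$x)
  cones <- dplyr::bind_rows(
    tibble::tibble(x = c(0, xmax), lo = c(0, xmax * object$band_a$m_min),
                   hi = c(0, xmax * object$band_a$m_max),
                   population = names[1]),
    tibble::tibble(x = c(0, xmax), lo = c(0, xmax * object$band_b$m_min),
                   hi = c(0, xmax * object$band_b$m_max),
                   population = names[2]))
  ggplot2::ggplot(pts, ggplot2::aes(colour = .data$population)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$x, y = .data$y),
                        alpha = 0.25, size = 0.7) +
    ggplot2::geom_ribbon(data = cones,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi,
                                      fill = .data$population),
                         alpha = 0.25, inherit.aes = FALSE) +
    ggplot2::geom_abline(slope = object$fit_a$m, intercept = 0) +
    ggplot2::geom_abline(slope = object$fit_b$m, intercept = 0) +
    ggplot2::labs(x = "time since fertilisation (h)", y = "predicted hpf")
}

#' Plot a training history
#'
#' @param object A trained `stage_model`.
#' @param ... Unused.
#' @export
autoplot.stage_model <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history")
  h <- tidyr_longer(object$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "MSE loss (hpf²)")
}

# minimal pivot (avoids a tidyr dependency for one call)
tidyr_longer <- function(h) {
  dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, loss = h$train_loss, set = "train"),
    tibble::tibble(epoch = h$epoch, loss = h$val_loss, set = "validation"))
}

#' Plot a saliency map
#'
#' @param object A `saliency_map`.
#' @param ... Unused.
#' @export
autoplot.saliency_map <- function(object, ...) {
  d <- dim(object)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    attribution = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$attribution)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
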