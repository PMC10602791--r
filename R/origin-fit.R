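#' Least-squares line through the origin
#'
#' Fits `y = m x` to a set of (true, predicted) points by least squares. The
#' closed-form slope is `m = sum(x*y) / sum(x^2)`. The goodness of fit is the
#' conventional `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the
#' mean of `y`; for a through-origin fit this can be negative, and it is
#' reported as `NA` when `SS_tot = 0` (all `y` identical).
#'
#' @param data A data frame of paired points, e.g. a prediction set.
#' @param x,y Names of the columns holding the abscissa (true hpf or elapsed
#'   time) and ordinate (predicted hpf).
#' @return An object of class `origin_fit` with elements `m`, `r_squared`,
#'   `n`, and the fitted data (for residual summaries and plotting).
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' d <- tibble::tibble(true_hpf = c(1, 2, 3), predicted_hpf = c(2, 4, 6))
#' fit_through_origin(d)$m # exactly 2
#' @export
fit_through_origin <- function(data, x = "true_hpf", y = "predicted_hpf") {
  xv <- pull_num(data, x)
  yv <- pull_num(data, y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) < 2L) stop("need at least 2 points to fit a line")
  if (all(xv == 0)) stop("all x values are zero; through-origin slope undefined")
  if (anyNA(xv) || anyNA(yv)) stop("missing values in fit input")
  m <- sum(xv * yv) / sum(xv^2)
  ss_res <- sum((yv - m * xv)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(
    list(m = m, r_squared = r2, n = length(xv), x = xv, y = yv,
         x_name = x, y_name = y),
    class = "origin_fit"
  )
}

# Accept either a data frame (column by name) or a bare numeric vector, so
# the stats layer is usable both piped and with raw vectors.
pull_num <- function(data, col) {
  if (is.data.frame(data)) {
    if (is.numeric(col) || !col %in% names(data)) {
      stop(sprintf("column '%s' not found in data", col))
    }
    as.numeric(data[[col]])
  } else {
    as.numeric(data)
  }
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> y = %.4f x  (R^2 = %s, n = %d)\n",
              x$m, ifelse(is.na(x$r_squared), "undefined",
                          sprintf("%.4f", x$r_squared)), x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.origin_fit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$m)
}

#' @export
glance.origin_fit <- function(x, ...) {
  tibble::tibble(m = x$m, r_squared = x$r_squared, n = x$n)
}

#' Residual summary of a through-origin fit
#'
#' Residuals are `r_i = y_i - m x_i`. Following the conventions of the
#' numerical routines this layer mirrors, the standard deviation uses
#' divisor `n` while the standard error of the mean uses the `n - 1` divisor
#' inside the SD before dividing by `sqrt(n)` (the two default `ddof`
#' conventions differ; both are reported as documented).
#'
#' @param data Data frame (or anything accepted by [fit_through_origin()])
#'   with the fitted columns; defaults to the data stored in `fit`.
#' @param fit An `origin_fit`.
#' @return A one-row tibble with `mean`, `sd`, `sem`, `n`.
#' @export
residual_summary <- function(data = NULL, fit) {
  stopifnot(inherits(fit, "origin_fit"))
  if (is.null(data)) {
    xv <- fit$x; yv <- fit$y
  } else {
    xv <- pull_num(data, fit$x_name)
    yv <- pull_num(data, fit$y_name)
  }
  n <- length(xv)
  if (n < 2L) stop("need at least 2 points for a residual summary")
  r <- yv - fit$m * xv
  sd_n <- sqrt(sum((r - mean(r))^2) / n)
  sem <- stats::sd(r) / sqrt(n) # sd() uses n - 1
  tibble::tibble(mean = mean(r), sd = sd_n, sem = sem, n = n)
}
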