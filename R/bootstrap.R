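#' Slope band from resampled through-origin fits
#'
#' Repeatedly draws random subsets of `k` points, fits `y = m x` to each, and
#' returns the minimum and maximum slope observed across `n_boot` resamples —
#' the confidence range used to decide whether two populations of embryos
#' develop at distinguishable rates. The default draws points *without*
#' replacement (random subsampling); classical bootstrap resampling with
#' replacement is available via `replace = TRUE`.
#'
#' @param data Data frame of prediction points (or numeric `x` with `y`
#'   supplied as a vector).
#' @param x,y Column names of abscissa and ordinate.
#' @param k Points per resample (2 <= k <= n). The reference analysis uses
#'   100 (outer band) and 200 (inner band).
#' @param n_boot Number of resamples; default 10000.
#' @param seed Integer seed; required for reproducibility.
#' @param replace Draw with replacement? Default `FALSE`.
#' @return A `slope_band` object with `m_min`, `m_max`, `k`, `n_boot`, and
#'   the vector of resampled `slopes`.
#' @export
bootstrap_slope_band <- function(data, x = "true_hpf", y = "predicted_hpf",
                                 k = 100, n_boot = 10000, seed = 1,
                                 replace = FALSE) {
  xv <- pull_num(data, x)
  yv <- if (is.data.frame(data)) pull_num(data, y) else as.numeric(y)
  n <- length(xv)
  if (length(yv) != n) stop("x and y must have equal length")
  if (k > n) stop(sprintf("resample size k = %d exceeds number of points n = %d", k, n))
  if (k < 2) stop("resample size k must be at least 2")
  slopes <- withr::with_seed(
    seed,
    boot_slopes_cpp(xv, yv, as.integer(k), as.integer(n_boot), isTRUE(replace))
  )
  structure(
    list(m_min = min(slopes), m_max = max(slopes),
         k = as.integer(k), n_boot = as.integer(n_boot),
         replace = isTRUE(replace), slopes = slopes),
    class = "slope_band"
  )
}

#' @export
print.slope_band <- function(x, ...) {
  cat(sprintf("<slope_band> [%.4f, %.4f]  (k = %d, %d resamples%s)\n",
              x$m_min, x$m_max, x$k, x$n_boot,
              if (x$replace) ", with replacement" else ""))
  invisible(x)
}

#' @export
tidy.slope_band <- function(x, ...) {
  tibble::tibble(m_min = x$m_min, m_max = x$m_max, k = x$k, n_boot = x$n_boot)
}

#' Can two slope bands tell their populations apart?
#'
#' Two populations are declared distinguishable when their slope bands are
#' disjoint intervals. The margin is the gap between the intervals; a
#' negative margin is the width of their overlap.
#'
#' @param a,b `slope_band` objects.
#' @return One-row tibble with `distinguishable` (logical) and `margin`.
#' @export
populations_distinguishable <- function(a, b) {
  stopifnot(inherits(a, "slope_band"), inherits(b, "slope_band"))
  margin <- max(a$m_min, b$m_min) - min(a$m_max, b$m_max)
  tibble::tibble(distinguishable = margin > 0, margin = margin)
}
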