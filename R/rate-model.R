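#' Temperature-scaling model of zebrafish developmental rate
#'
#' Constructs the standard Kimmel temperature model relating hours of
#' development at an incubation temperature `T` to the equivalent hours post
#' fertilisation (hpf) at the 28.5 degC reference:
#' \deqn{H_T = h / (0.055 \, T - c)}
#' where `h` is hpf at the reference temperature and `c` is a constant
#' (0.57 degC). The quantity `0.055 T - c` is the *relative developmental
#' rate*: stage units gained per clock hour at temperature `T`.
#'
#' @param c Rate-model constant in degC. Default 0.57.
#' @param slope_coeff Temperature coefficient per degC. Default 0.055.
#' @param reference_temperature Reference incubation temperature in degC
#'   (28.5, the convention under which hpf is reported).
#'
#' @return An object of class `rate_model`.
#' @examples
#' m <- rate_model()
#' relative_rate(25, m) # 0.805
#' @export
rate_model <- function(c = 0.57, slope_coeff = 0.055, reference_temperature = 28.5) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0,
            is.numeric(slope_coeff), length(slope_coeff) == 1L, slope_coeff > 0)
  structure(
    list(c = c, slope_coeff = slope_coeff,
         reference_temperature = reference_temperature),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> rate(T) = %g*T - %g  (reference %g degC, rate %g)\n",
              x$slope_coeff, x$c, x$reference_temperature,
              x$slope_coeff * x$reference_temperature - x$c))
  invisible(x)
}

#' Relative developmental rate at a temperature
#'
#' Evaluates `0.055*T - c`: the expected slope of a
#' developmental-stage-versus-clock-time line for embryos incubated at `T`,
#' relative to hpf at the 28.5 degC reference. At 25.0 degC this is 0.805,
#' i.e. embryos develop at ~80.5% of the reference rate.
#'
#' @param temperature Incubation temperature in degC.
#' @param model A [rate_model()].
#' @return Unitless rate (vectorised over `temperature`).
#' @export
relative_rate <- function(temperature, model = rate_model()) {
  stopifnot(inherits(model, "rate_model"), is.numeric(temperature))
  rate <- model$slope_coeff * temperature - model$c
  if (any(rate <= 0)) {
    stop(sprintf(
      "nonpositive developmental rate at %s degC: temperature must exceed c/slope_coeff = %.4g degC",
      paste(signif(temperature[rate <= 0], 4), collapse = ", "),
      model$c / model$slope_coeff
    ))
  }
  rate
}

#' Standard-equivalent developmental stage after elapsed time
#'
#' Converts clock time since fertilisation at incubation temperature `T`
#' into the equivalent hpf at the 28.5 degC reference:
#' `h = t * (0.055*T - c)`. Linear in `t`, increasing in `T`.
#'
#' @param t_hours Hours elapsed since fertilisation (>= 0).
#' @param temperature Incubation temperature in degC.
#' @param model A [rate_model()].
#' @return Stage in reference-equivalent hpf.
#' @export
stage_at_time <- function(t_hours, temperature, model = rate_model()) {
  stopifnot(is.numeric(t_hours), all(t_hours >= 0))
  t_hours * relative_rate(temperature, model)
}
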