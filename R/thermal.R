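#' First-order thermal model
#'
#' A single-exponential estimate of the medium temperature rise under
#' stimulation: driving the matrix at duty cycle `d` heats the medium towards
#' a plateau of `gain_K * d` with time constant `tau_s`. The default
#' `tau_s = 1200` s makes the curve >= 95% saturated after one hour,
#' consistent with a temperature plateau reached after about an hour of
#' repetitive stimulation. The gain has no hardware-anchored default; this
#' module is an estimate, not a measurement.
#'
#' @param gain_K Plateau temperature rise at duty cycle 1 (K).
#' @param tau_s Time constant (s), > 0.
#' @return An object of class `thermal_model`.
#' @export
thermal_model <- function(gain_K = 1.0, tau_s = 1200) {
  stopifnot(gain_K >= 0, tau_s > 0)
  structure(list(gain_K = gain_K, tau_s = tau_s), class = "thermal_model")
}

#' Estimated medium temperature rise
#'
#' `dT(t) = gain_K * duty * (1 - exp(-t / tau_s))`: zero at `t = 0`,
#' approaching the plateau `gain_K * duty` for `t >> tau_s`. Longer and more
#' frequent stimulation (higher duty cycle) gives a proportionally higher
#' temperature rise.
#'
#' @param t_s Time since stimulation onset (s), >= 0; vectorized.
#' @param duty Duty cycle in `[0, 1]` (see [duty_cycle()]).
#' @param model A `thermal_model`.
#' @return Temperature rise in kelvin.
#' @examples
#' temp_rise(3600, 0.5)  # ~95% of the half-duty plateau
#' @export
temp_rise <- function(t_s, duty, model = thermal_model()) {
  if (any(duty < 0 | duty > 1)) stop("duty cycle must lie in [0, 1]")
  if (any(t_s < 0)) stop("time must be >= 0")
  model$gain_K * duty * (1 - exp(-t_s / model$tau_s))
}

#' Export a temperature-rise curve as CSV
#'
#' @param t_s Vector of times (s).
#' @param duty Duty cycle.
#' @param model A `thermal_model`.
#' @param path Output CSV path.
#' @export
write_temp_curve <- function(t_s, duty, model = thermal_model(), path) {
  utils::write.csv(data.frame(t_s = t_s,
                              dT_K = temp_rise(t_s, duty, model)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
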