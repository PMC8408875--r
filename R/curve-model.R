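#' Parametric postprandial concentration curve
#'
#' A smooth stand-in for observed meal-response curves: a baseline plus a
#' sum of Gaussian peaks, one per meal excursion. The form is chosen for
#' smoothness and closed-form features (peak height at `t = peak_time` is
#' `baseline + amplitude`), not as a physiological model.
#'
#' @param t Time in minutes (vectorized).
#' @param amplitude Peak amplitudes (mmol/L), one per peak.
#' @param peak_time Peak times (minutes), same length as `amplitude`.
#' @param width Gaussian widths (minutes), same length as `amplitude`;
#'   must be strictly positive.
#' @param baseline Fasting concentration (mmol/L).
#' @return Concentrations at `t` (mmol/L):
#'   `baseline + sum_k amplitude_k * exp(-(t - peak_time_k)^2 / (2 width_k^2))`.
#' @examples
#' curve_model(30, amplitude = 2.1, peak_time = 30, width = 25, baseline = 4.9)
#' @export
curve_model <- function(t, amplitude, peak_time, width, baseline = 0) {
  check_numeric(t, "t")
  k <- length(amplitude)
  if (length(peak_time) != k || length(width) != k) {
    pp_stop("`amplitude`, `peak_time` and `width` must have equal lengths")
  }
  if (k > 0 && any(!is.finite(width) | width <= 0)) {
    pp_stop("peak `width` values must be strictly positive")
  }
  out <- rep(baseline, length(t))
  for (i in seq_len(k)) {
    out <- out + amplitude[i] * exp(-(t - peak_time[i])^2 / (2 * width[i]^2))
  }
  out
}
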