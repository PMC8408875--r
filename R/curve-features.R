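# Featurization of timed postprandial concentration series. All operations
# are defined on the sampled points only: no smoothing, no interpolation
# beyond the trapezoids implied by the sampling grid.

check_curve <- function(times, values) {
  check_numeric(times, "times")
  check_numeric(values, "values")
  if (length(times) != length(values)) {
    pp_stop("`times` and `values` must have equal lengths")
  }
  if (length(times) < 2) pp_stop("a curve needs at least 2 samples")
  if (any(diff(times) <= 0)) pp_stop("`times` must be strictly increasing")
  if (times[1] != 0) pp_stop("the first sample must be the fasting value at t = 0")
  invisible(NULL)
}

#' Incremental area under a postprandial curve
#'
#' Trapezoidal area of the positive increment above the fasting (t = 0)
#' value over `[0, window_end]` minutes: values are baseline-subtracted,
#' clipped at zero at the sampled points (Wolever-style incremental AUC,
#' ignoring excursions below baseline), then integrated by the trapezoid
#' rule. Set `convention = "net"` for the signed net area instead.
#'
#' @param times Sampling times in minutes, strictly increasing, first = 0.
#' @param values Concentrations (mmol/L), same length as `times`.
#' @param window_end Upper integration limit in minutes; must not exceed
#'   the last sampled time and at least two samples must fall in
#'   `[0, window_end]`.
#' @param convention `"positive"` (default) clips below-baseline increments
#'   to zero; `"net"` keeps them.
#' @return Incremental area in mmol/L times min.
#' @examples
#' iauc(c(0, 60, 120), c(5, 7, 5), 120) # 120
#' @export
iauc <- function(times, values, window_end, convention = c("positive", "net")) {
  convention <- match.arg(convention)
  check_curve(times, values)
  if (window_end > max(times)) {
    pp_stop("`window_end` exceeds the last sampled time")
  }
  keep <- times <= window_end + 1e-9
  if (sum(keep) < 2) {
    pp_stop("insufficient data: fewer than 2 samples in [0, window_end]")
  }
  inc <- values[keep] - values[1]
  if (convention == "positive") inc <- pmax(inc, 0)
  trapz(times[keep], inc)
}

#' Rise from fasting at a sampled time
#'
#' `value(at) - value(0)`; may be negative. `at` must be one of the sampled
#' times -- no interpolation is performed.
#'
#' @inheritParams iauc
#' @param at Sampled time (minutes).
#' @return Rise in mmol/L.
#' @examples
#' rise_from_fasting(c(0, 30, 60), c(4.91, 7.01, 6.2), 30) # 2.1
#' @export
rise_from_fasting <- function(times, values, at) {
  check_curve(times, values)
  i <- which(abs(times - at) < 1e-9)
  if (length(i) == 0) {
    pp_stop(sprintf(
      "time %s min is not sampled (available: %s)",
      format(at), paste(times, collapse = ", ")
    ))
  }
  values[i[1]] - values[1]
}

#' Maximum sampled concentration in a time window
#'
#' Maximum sampled value within the closed interval `window` and the time
#' at which it occurs; ties resolve to the earliest time.
#'
#' @inheritParams iauc
#' @param window Numeric length-2 `c(t_lo, t_hi)` in minutes (inclusive).
#' @return A named list with `cmax` (mmol/L) and `tmax` (minutes).
#' @examples
#' windowed_max(c(0, 15, 30, 60, 120), c(4.9, 6, 7, 6.5, 5.2), c(0, 120))
#' @export
windowed_max <- function(times, values, window) {
  check_curve(times, values)
  if (length(window) != 2 || window[2] < window[1]) {
    pp_stop("`window` must be c(t_lo, t_hi) with t_lo <= t_hi")
  }
  keep <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(keep) == 0) {
    pp_stop("insufficient data: no samples in the requested window")
  }
  v <- values[keep]
  i <- keep[which.max(v)] # which.max returns the first (earliest) maximum
  list(cmax = values[i], tmax = times[i])
}

require_times <- function(times, need, analyte) {
  miss <- need[!vapply(need, function(t) any(abs(times - t) < 1e-9), logical(1))]
  if (length(miss) > 0) {
    pp_stop(sprintf(
      "%s curve is missing required time point(s): %s min",
      analyte, paste(miss, collapse = ", ")
    ))
  }
}

#' Glycemic features of one glucose curve
#'
#' The seven named glycemic summaries: fasting value, 1-h and 2-h
#' incremental AUCs, 30-min and 1-h rises from fasting, and the windowed
#' maxima of the first (0--120 min) and second (240--360 min) glucose peaks
#' with their times.
#'
#' @inheritParams iauc
#' @return A one-row tibble with columns `glu_fasting`, `glu_1h_iauc`,
#'   `glu_2h_iauc`, `glu_30min_rise`, `glu_1h_rise`, `glu_max1`,
#'   `glu_tmax1`, `glu_max2`, `glu_tmax2`.
#' @export
glycemic_features <- function(times, values) {
  check_curve(times, values)
  require_times(times, c(30, 60, 120), "glucose")
  m1 <- windowed_max(times, values, c(0, 120))
  m2 <- windowed_max(times, values, c(240, 360))
  tibble::tibble(
    glu_fasting = values[1],
    glu_1h_iauc = iauc(times, values, 60),
    glu_2h_iauc = iauc(times, values, 120),
    glu_30min_rise = rise_from_fasting(times, values, 30),
    glu_1h_rise = rise_from_fasting(times, values, 60),
    glu_max1 = m1$cmax, glu_tmax1 = m1$tmax,
    glu_max2 = m2$cmax, glu_tmax2 = m2$tmax
  )
}

#' Lipemic features of one triglyceride curve
#'
#' The six named lipemic summaries: fasting value, 6-h incremental AUC,
#' 6-h rise from fasting, 0--360 min windowed maximum with its time, and
#' the 4-h and 6-h concentrations.
#'
#' @inheritParams iauc
#' @return A one-row tibble with columns `tg_fasting`, `tg_6h_iauc`,
#'   `tg_6h_rise`, `tg_max`, `tg_tmax`, `tg_at_4h`, `tg_at_6h`.
#' @export
lipemic_features <- function(times, values) {
  check_curve(times, values)
  require_times(times, c(240, 360), "TG")
  m <- windowed_max(times, values, c(0, 360))
  tibble::tibble(
    tg_fasting = values[1],
    tg_6h_iauc = iauc(times, values, 360),
    tg_6h_rise = rise_from_fasting(times, values, 360),
    tg_max = m$cmax, tg_tmax = m$tmax,
    tg_at_4h = rise_from_fasting(times, values, 240) + values[1],
    tg_at_6h = rise_from_fasting(times, values, 360) + values[1]
  )
}

#' Extract the 13 postprandial features for every participant
#'
#' Maps [glycemic_features()] and [lipemic_features()] over a long curve
#' table and joins the results into one wide row per participant (13
#' features plus 3 peak-time columns).
#'
#' @param curves Long tibble with columns `participant_id`, `analyte`
#'   (`"glucose"` / `"TG"`), `time_min`, `value`, e.g. the `curves` element
#'   of [simulate_cohort()].
#' @return A tibble with one row per participant.
#' @examples
#' dat <- simulate_cohort(cohort_config(n_participants = 20, seed = 1))
#' extract_curve_features(dat$curves)
#' @export
extract_curve_features <- function(curves) {
  check_columns(curves, c("participant_id", "analyte", "time_min", "value"), "curves")
  one <- function(df, fn) {
    df <- dplyr::arrange(df, .data$time_min)
    fn(df$time_min, df$value)
  }
  glu <- curves |>
    dplyr::filter(.data$analyte == "glucose") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x, glycemic_features)) |>
    dplyr::ungroup()
  tg <- curves |>
    dplyr::filter(.data$analyte == "TG") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x, lipemic_features)) |>
    dplyr::ungroup()
  dplyr::full_join(glu, tg, by = "participant_id")
}

#' Canonical postprandial feature names
#'
#' The 13 model-input curve summaries (peak times are emitted by
#' [extract_curve_features()] but excluded from default model inputs).
#' `"postprandial"` drops the two fasting values, leaving the features
#' that describe the meal response itself.
#'
#' @param which `"all"` (13 names) or `"postprandial"` (11 names).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(which = c("all", "postprandial")) {
  which <- match.arg(which)
  all13 <- c(
    "glu_fasting", "glu_1h_iauc", "glu_2h_iauc", "glu_30min_rise",
    "glu_1h_rise", "glu_max1", "glu_max2",
    "tg_fasting", "tg_6h_iauc", "tg_6h_rise", "tg_max", "tg_at_4h", "tg_at_6h"
  )
  if (which == "all") all13 else setdiff(all13, c("glu_fasting", "tg_fasting"))
}
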