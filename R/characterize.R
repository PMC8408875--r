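# Descriptive analytics for the postprandial inflammatory response.

#' Log-transform a marker value as ln(x + 1)
#'
#' The standard variance-stabilizing transform applied to IL-6 before
#' correlation and ANOVA analyses.
#'
#' @param x Non-negative marker values.
#' @return `log(x + 1)`.
#' @export
ln_plus_one <- function(x) {
  check_numeric(x, "x")
  if (any(x < 0, na.rm = TRUE)) pp_stop("`x` must be non-negative")
  log(x + 1)
}

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`. Use [format_percent()] to match
#' report print conventions (integers rounded, one-decimal truncated).
#'
#' @param baseline Baseline value(s), strictly positive.
#' @param followup Follow-up value(s).
#' @return Percent change.
#' @examples
#' percent_change(0.48, 1.29) # 168.75, printed as 169%
#' @export
percent_change <- function(baseline, followup) {
  check_numeric(baseline, "baseline")
  check_numeric(followup, "followup")
  if (any(baseline <= 0, na.rm = TRUE)) {
    pp_stop("`baseline` must be strictly positive for a percent change")
  }
  100 * (followup - baseline) / baseline
}

#' Responder summary for one inflammatory marker
#'
#' Classifies participants by their 6-h minus fasting change: risers
#' (change `> epsilon`), decliners (`< -epsilon`) and unchanged (within the
#' tolerance band), and summarizes the risers' mean fasting / 6-h values,
#' mean rise and percent rise (computed from the responder means).
#'
#' @param markers Long tibble with columns `participant_id`, `marker`,
#'   `time_h`, `value` (times 0 and 6 required).
#' @param marker Marker name to summarize (e.g. `"GlycA"`, `"IL-6"`).
#' @param epsilon Tolerance band around zero defining "unchanged";
#'   default 0 (strict rise).
#' @return A one-row tibble: `n_total`, `n_rising`, `fraction_rising`,
#'   `fraction_declining`, `fraction_unchanged`, `mean_rise`, `pct_rise`
#'   (cohort-mean percent change), `responder_mean_fasting`,
#'   `responder_mean_6h`, `responder_mean_rise`, `responder_pct_rise`.
#'   Responder fields are `NA` when nobody rises.
#' @export
responder_summary <- function(markers, marker, epsilon = 0) {
  check_columns(markers, c("participant_id", "marker", "time_h", "value"), "markers")
  wide <- markers |>
    dplyr::filter(.data$marker == !!marker, .data$time_h %in% c(0, 6)) |>
    tidyr::pivot_wider(
      id_cols = "participant_id", names_from = "time_h",
      names_prefix = "h", values_from = "value"
    )
  if (all(c("h0", "h6") %in% names(wide))) {
    wide <- dplyr::filter(wide, !is.na(.data$h0) & !is.na(.data$h6))
  } else {
    wide <- wide[0, ]
  }
  if (nrow(wide) == 0) {
    pp_stop(sprintf("no participants with both 0 h and 6 h values for %s", marker))
  }
  rise <- wide$h6 - wide$h0
  rising <- rise > epsilon
  declining <- rise < -epsilon
  n <- nrow(wide)
  res <- tibble::tibble(
    marker = marker,
    n_total = n,
    n_rising = sum(rising),
    fraction_rising = mean(rising),
    fraction_declining = mean(declining),
    fraction_unchanged = mean(!rising & !declining),
    mean_rise = mean(rise),
    pct_rise = percent_change(mean(wide$h0), mean(wide$h6))
  )
  if (any(rising)) {
    m0 <- mean(wide$h0[rising])
    m6 <- mean(wide$h6[rising])
    res$responder_mean_fasting <- m0
    res$responder_mean_6h <- m6
    res$responder_mean_rise <- m6 - m0
    res$responder_pct_rise <- percent_change(m0, m6)
  } else {
    res$responder_mean_fasting <- NA_real_
    res$responder_mean_6h <- NA_real_
    res$responder_mean_rise <- NA_real_
    res$responder_pct_rise <- NA_real_
  }
  res
}

#' Cross-sectional coefficient of variation
#'
#' Between-participant dispersion of a marker at one time point:
#' `cv_pct = 100 * sd / mean` with the sample SD (n - 1 denominator).
#'
#' @param values Concentrations at one time point (n >= 2, mean > 0).
#' @return A one-row tibble with `n`, `mean`, `sd`, `cv_pct`.
#' @export
cross_sectional_cv <- function(values) {
  check_numeric(values, "values")
  values <- values[!is.na(values)]
  if (length(values) < 2) pp_stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m <= 0) pp_stop("CV undefined: mean must be > 0")
  s <- sd(values)
  tibble::tibble(n = length(values), mean = m, sd = s, cv_pct = 100 * s / m)
}

#' Levene's test of variance heterogeneity
#'
#' One-way ANOVA on absolute deviations from the group center. The classic
#' Levene statistic uses the group mean as center; `center = "median"`
#' gives the Brown--Forsythe variant.
#'
#' @param values Numeric observations.
#' @param group Group labels, same length as `values`; at least 2 groups,
#'   each with n >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return A one-row tibble with `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  check_numeric(values, "values")
  if (length(values) != length(group)) {
    pp_stop("`values` and `group` must have equal lengths")
  }
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  g <- factor(group[keep])
  sizes <- table(g)
  if (length(sizes) < 2) pp_stop("need at least 2 groups")
  if (any(sizes < 2)) pp_stop("every group needs at least 2 observations")
  cfun <- if (center == "mean") mean else median
  centers <- tapply(values, g, cfun)
  absdev <- abs(values - centers[as.character(g)])
  a <- anova(lm(absdev ~ g))
  tibble::tibble(
    statistic = a[["F value"]][1],
    df1 = a[["Df"]][1], df2 = a[["Df"]][2],
    p_value = a[["Pr(>F)"]][1]
  )
}

#' Pearson correlations of curve features with inflammatory markers
#'
#' Pairwise-complete Pearson correlation of every feature column with every
#' marker-by-time value, with a two-sided t-test p-value and a significance
#' flag at `alpha` (the analogue of an "X = nonsignificant" correlation
#' grid). IL-6 values are ln(x + 1)-transformed before correlating; GlycA
#' is used raw.
#'
#' @param features Wide tibble from [extract_curve_features()]
#'   (`participant_id` + numeric feature columns).
#' @param markers Long marker tibble (`participant_id`, `marker`, `time_h`,
#'   `value`).
#' @param alpha Significance threshold, default 0.05.
#' @return A tibble with one row per feature x marker x time:
#'   `feature`, `marker`, `time_h`, `n`, `r`, `p_value`, `significant`.
#'   Entries with fewer than 3 complete pairs are returned with `NA`
#'   estimates and flagged in the `insufficient` column.
#' @export
correlation_matrix <- function(features, markers, alpha = 0.05) {
  check_columns(features, "participant_id", "features")
  check_columns(markers, c("participant_id", "marker", "time_h", "value"), "markers")
  feat_cols <- setdiff(names(features), "participant_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  mk <- markers
  il6 <- mk$marker == "IL-6"
  mk$value[il6] <- ln_plus_one(mk$value[il6])
  combos <- mk |> dplyr::distinct(.data$marker, .data$time_h)
  purrr::pmap_dfr(combos, function(marker, time_h) {
    mv <- mk |>
      dplyr::filter(.data$marker == !!marker, .data$time_h == !!time_h) |>
      dplyr::select("participant_id", marker_value = "value")
    joined <- dplyr::inner_join(features, mv, by = "participant_id")
    purrr::map_dfr(feat_cols, function(fc) {
      x <- joined[[fc]]
      y <- joined$marker_value
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        return(tibble::tibble(
          feature = fc, marker = marker, time_h = time_h, n = sum(ok),
          r = NA_real_, p_value = NA_real_, significant = NA,
          insufficient = TRUE
        ))
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      tibble::tibble(
        feature = fc, marker = marker, time_h = time_h, n = sum(ok),
        r = unname(ct$estimate), p_value = ct$p.value,
        significant = ct$p.value < alpha, insufficient = FALSE
      )
    })
  })
}

#' Repeated-measures interaction of a marker trajectory with a factor
#'
#' Mixed two-way ANOVA with time (0/4/6 h) as the within-participant factor
#' and sex or an age-group dichotomy (median split) as the between factor;
#' returns the interaction term. Participants missing any time point are
#' dropped (with a message giving the count). IL-6 is ln(x + 1)-transformed.
#'
#' @param markers Long marker tibble (`participant_id`, `marker`, `time_h`,
#'   `value`).
#' @param covariates Tibble with `participant_id` and the between-factor
#'   source columns (`sex`, `age`).
#' @param marker Marker to analyze.
#' @param between `"sex"` or `"age_group"`.
#' @return A one-row tibble: `marker`, `between`, `term`, `statistic` (F),
#'   `df1`, `df2`, `p_value`, `n_used`, `n_dropped`.
#' @export
rm_interaction_test <- function(markers, covariates, marker,
                                between = c("sex", "age_group")) {
  between <- match.arg(between)
  check_columns(markers, c("participant_id", "marker", "time_h", "value"), "markers")
  need <- if (between == "sex") "sex" else "age"
  check_columns(covariates, c("participant_id", need), "covariates")

  d <- markers |>
    dplyr::filter(.data$marker == !!marker) |>
    dplyr::inner_join(covariates, by = "participant_id")
  if (marker == "IL-6") d$value <- ln_plus_one(d$value)
  if (between == "age_group") {
    med <- median(d$age[!duplicated(d$participant_id)])
    d$grp <- factor(ifelse(d$age > med, "older", "younger"))
  } else {
    d$grp <- factor(d$sex)
  }
  if (nlevels(d$grp) < 2) pp_stop("the between factor needs at least 2 levels")

  times <- sort(unique(d$time_h))
  complete <- d |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == length(times))
  n_all <- dplyr::n_distinct(d$participant_id)
  n_used <- nrow(complete)
  if (n_used < n_all) {
    message(sprintf(
      "%d participant(s) missing a time point were dropped", n_all - n_used
    ))
  }
  d <- dplyr::semi_join(d, complete, by = "participant_id")
  d$time_f <- factor(d$time_h)
  d$pid <- factor(d$participant_id)

  fit <- aov(value ~ grp * time_f + Error(pid), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  i <- grep("grp:time_f", rownames(within))
  tibble::tibble(
    marker = marker, between = between, term = "group:time",
    statistic = within[i, "F value"],
    df1 = within[i, "Df"], df2 = within["Residuals", "Df"],
    p_value = within[i, "Pr(>F)"],
    n_used = n_used, n_dropped = n_all - n_used
  )
}
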