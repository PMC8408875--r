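# Independent oracles used to cross-check the implementation. Each oracle
# recomputes a quantity by brute force / enumeration / simulation and never
# calls the code path it checks.

# AUC by exhaustive pair counting: (concordant + 0.5 * ties) / all pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) {
    for (y in neg) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(pos) * length(neg))
}

# Incremental AUC by fine-grid Riemann sum over the piecewise-linear curve
# of clipped increments.
oracle_iauc <- function(times, values, window_end, n_grid = 1e4) {
  inc <- pmax(values - values[1], 0)
  f <- stats::approxfun(times, inc)
  keep <- times <= window_end + 1e-9
  bounds <- times[keep]
  total <- 0
  for (s in seq_len(length(bounds) - 1)) {
    # midpoint rule per sampled segment (the curve is linear within it)
    g <- seq(bounds[s], bounds[s + 1], length.out = n_grid + 1)
    mid <- (g[-1] + g[-length(g)]) / 2
    total <- total + sum(f(mid)) * (bounds[s + 1] - bounds[s]) / n_grid
  }
  total
}

# IVW estimate by brute-force grid minimization of the weighted residual
# sum of squares (two-stage grid; returns estimate and final resolution).
oracle_ivw_grid <- function(h, half_width = 3) {
  w <- 1 / h$se_out^2
  obj <- function(b) {
    vapply(b, function(bb) sum(w * (h$beta_out - bb * h$beta_exp)^2), 0)
  }
  lo <- -half_width
  hi <- half_width
  for (stage in 1:4) {
    grid <- seq(lo, hi, length.out = 2001)
    best <- grid[which.min(obj(grid))]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  list(beta = best, resolution = step)
}

# Independent spreadsheet-style recomputation of the fit-index formulas.
oracle_fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n) {
  d_m <- chi2_m - df_m
  d_b <- chi2_b - df_b
  cfi <- 1 - max(d_m, 0) / max(d_b, d_m, 0)
  if (!is.finite(cfi)) cfi <- 1
  tli <- ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  rmsea <- sqrt(max(d_m, 0) / (df_m * (n - 1)))
  c(cfi = cfi, tli = tli, rmsea = rmsea)
}

# Build a harmonized-instrument tibble directly for estimator tests.
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01) {
  J <- length(beta_exp)
  tibble::tibble(
    snp = sprintf("s%02d", seq_len(J)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, J),
    beta_out = beta_out, se_out = rep_len(se_out, J)
  )
}

# Monte-Carlo oracle of the cohort's planted linear-Gaussian system: an
# independent re-simulation of the scalar model (no curves) from the truth
# record, returning the feature-marker correlations of interest.
oracle_cohort_correlations <- function(truth, n = 1e6, seed = 99) {
  set.seed(seed)
  vfm <- pmax(rnorm(n, truth$vfm["mean"], truth$vfm["sd"]), 0.05)
  z_vfm <- (vfm - truth$vfm["mean"]) / truth$vfm["sd"]
  e_vt <- truth$effect_vfm_on_tg
  tb <- truth$tg_baseline
  z_raw <- e_vt * z_vfm + sqrt(1 - e_vt^2) * rnorm(n)
  tg_base <- pmax(tb["mean"] + tb["sd"] * z_raw, 0.1)
  tp <- truth$tg_peak
  amp <- pmax(rnorm(n, tp$amplitude, tp$amplitude_sd), 0.05)
  pt <- rnorm(n, tp$peak_time, tp$peak_time_sd)
  tg_fast <- tg_base + amp * exp(-pt^2 / (2 * tp$width^2))
  z_tg <- (tg_fast - tb["mean"]) / tb["sd"]
  k6 <- exp(-(360 - pt)^2 / (2 * tp$width^2))
  z_t6 <- (tg_base + amp * k6 - truth$mu_t6) / truth$sd_t6
  gp <- truth$glucose_peaks
  gb <- pmax(rnorm(n, truth$glucose_baseline["mean"], truth$glucose_baseline["sd"]), 3)
  a1 <- pmax(rnorm(n, gp$amplitude[1], gp$amplitude_sd[1]), 0.2)
  a2 <- pmax(rnorm(n, gp$amplitude[2], gp$amplitude_sd[2]), 0.2)
  z_a1 <- (a1 - gp$amplitude[1]) / gp$amplitude_sd[1]
  rn <- truth$glyca_noise_sd
  g0 <- truth$effect_tg_on_glyca * z_tg +
    truth$effect_vfm_direct_on_glyca * z_vfm + rn[1] * rnorm(n)
  g6 <- truth$effect_glyca0_on_glyca6 * g0 +
    truth$effect_tg6_on_glyca6 * z_t6 +
    truth$effect_glucose_on_glyca6 * z_a1 + rn[3] * rnorm(n)
  gs <- truth$glyca_scale
  glyca6 <- pmax(gs["pp6_mean"] + gs["pp6_sd"] * g6, 0.2)
  nm <- truth$noise_sd
  tg6_meas <- pmax(tg_base + amp * k6 + rnorm(n, 0, nm["tg"]), 0.01)
  # measured first glucose peak: max over the sampled 0-120 min window
  wt <- c(0, 15, 30, 60, 120)
  gvals <- lapply(wt, function(t) {
    pmax(gb + a1 * exp(-(t - gp$peak_time[1])^2 / (2 * gp$width[1]^2)) +
           a2 * exp(-(t - gp$peak_time[2])^2 / (2 * gp$width[2]^2)) +
           rnorm(n, 0, nm["glucose"]), 0.1)
  })
  glu_max1 <- Reduce(pmax, gvals)
  c(
    r_tg6_glyca6 = cor(tg6_meas, glyca6),
    r_glumax1_glyca6 = cor(glu_max1, glyca6)
  )
}

# Small default-condition cohort shared across tests (built once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- simulate_cohort(cohort_config(n_participants = 400, seed = 402))
      feats <- extract_curve_features(dat$curves)
      mw <- tidyr::pivot_wider(
        dat$markers,
        id_cols = "participant_id", names_from = c("marker", "time_h"),
        values_from = "value", names_glue = "{marker}_{time_h}h"
      )
      names(mw) <- tolower(gsub("-", "", names(mw)))
      cache <<- list(
        data = dat, features = feats,
        model = dplyr::inner_join(feats, mw, by = "participant_id")
      )
    }
    cache
  }
})
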