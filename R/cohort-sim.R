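#' Configuration for the synthetic metabolic-challenge cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a cohort of
#' healthy adults given a breakfast challenge meal at 0 h and a lunch at 4 h,
#' with glucose sampled on a dense 0--360 min grid, triglycerides (TG) on an
#' hourly grid, and the inflammatory markers GlycA and IL-6 measured at 0, 4
#' and 6 h. Default curve parameters reproduce the canonical cohort-mean
#' shapes: a two-peak glucose curve (first peak at 30 min, second about 1 h
#' after lunch) and a late single-peak TG curve, with GlycA coupled strongly
#' to TG and weakly to glucose, and IL-6 rising postprandially independent of
#' either.
#'
#' The planted structural part is a linear-Gaussian system on standardized
#' latent scores: visceral fat mass (VFM) -> fasting TG -> fasting GlycA,
#' with a direct VFM -> GlycA path, and 6-h GlycA driven by fasting GlycA,
#' the (latent) 6-h TG value and the first glucose peak amplitude. All
#' planted slopes are standardized and recorded in the returned dataset's
#' `truth` element.
#'
#' @param n_participants Cohort size (>= 2). Default 1000.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @param sampling_times Glucose sampling grid in minutes; strictly
#'   increasing, must include 0, 30, 60, 120, 240 and 360.
#' @param tg_times TG sampling grid in minutes; strictly increasing, must
#'   include 0, 240 and 360.
#' @param glucose_baseline,tg_baseline Named `c(mean =, sd =)` for the
#'   baseline concentration distributions (mmol/L). The observed fasting
#'   value is the curve at t = 0, i.e. baseline plus the first peak's
#'   Gaussian tail; the glucose defaults are chosen so the observed
#'   fasting mean/SD land at about 4.91 +/- 0.50 mmol/L.
#' @param glucose_peaks List with `amplitude`, `amplitude_sd`, `peak_time`,
#'   `width` (each length 2, minutes / mmol/L) for the two glucose peaks.
#' @param tg_peak List with scalar `amplitude`, `amplitude_sd`, `peak_time`,
#'   `peak_time_sd`, `width` for the single TG peak. `peak_time_sd` is the
#'   between-participant SD of the lipemic peak time (min): lipemia timing
#'   varies between people, which decorrelates the 4-h and 6-h TG values.
#' @param effect_vfm_on_tg,effect_tg_on_glyca,effect_vfm_direct_on_glyca
#'   Standardized planted slopes of the fasting-state system.
#' @param effect_tg6_on_glyca6,effect_glucose_on_glyca6,effect_glyca0_on_glyca6
#'   Standardized planted slopes into 6-h GlycA.
#' @param glyca_noise_sd Residual SDs (latent, standardized scale) for
#'   fasting, 4-h and 6-h GlycA. `NULL` (default) chooses residuals so each
#'   latent score has unit variance; pass `c(0, 0, 0)` for a noiseless system.
#' @param glyca_scale Named vector mapping latent GlycA scores to mmol/L
#'   (`fasting_mean`, `fasting_sd`, `pp4_mean`, `pp4_sd`, `pp6_mean`,
#'   `pp6_sd`).
#' @param il6 Named vector of IL-6 marker-unit parameters: fasting mean/SD
#'   and the 4-h and 6-h rise mean/SD. IL-6 rises are drawn independently of
#'   every glucose/TG quantity.
#' @param noise_sd Named measurement noise SDs `c(glucose =, tg =)` (mmol/L)
#'   added to every sampled curve value.
#' @param sex_rise_shift Named `c(glyca =, il6 =)`: shift (in 6-h scale SDs /
#'   rise SDs) added to the male 6-h response, default 0 for both; nonzero
#'   values plant a sex-by-time interaction.
#' @param age_range,male_fraction,bmi,weight,vfm Covariate distributions
#'   (age uniform in years; sex Bernoulli; BMI kg/m^2; weight kg; VFM in
#'   arbitrary mass units).
#' @param microbiome_pc_sd SDs of the 10 mutually independent microbiome
#'   principal-component covariates.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 1000,
                          seed = 1L,
                          sampling_times = c(0, 15, 30, 60, 120, 180, 240, 270, 300, 360),
                          tg_times = c(0, 60, 120, 180, 240, 270, 300, 360),
                          glucose_baseline = c(mean = 4.21, sd = 0.45),
                          glucose_peaks = list(
                            amplitude = c(2.80, 2.26),
                            amplitude_sd = c(0.90, 0.80),
                            peak_time = c(30, 300),
                            width = c(18, 40)
                          ),
                          tg_baseline = c(mean = 1.05, sd = 0.50),
                          tg_peak = list(
                            amplitude = 1.06, amplitude_sd = 0.55,
                            peak_time = 300, peak_time_sd = 30, width = 75
                          ),
                          effect_vfm_on_tg = 0.30,
                          effect_tg_on_glyca = 0.57,
                          effect_vfm_direct_on_glyca = 0.17,
                          effect_tg6_on_glyca6 = 0.70,
                          effect_glucose_on_glyca6 = 0.15,
                          effect_glyca0_on_glyca6 = 0.30,
                          glyca_noise_sd = NULL,
                          glyca_scale = c(
                            fasting_mean = 1.32, fasting_sd = 0.18,
                            pp4_mean = 1.35, pp4_sd = 0.22,
                            pp6_mean = 1.38, pp6_sd = 0.28
                          ),
                          il6 = c(
                            fasting_mean = 0.48, fasting_sd = 0.28,
                            rise4_mean = 0.55, rise4_sd = 0.41,
                            rise6_mean = 0.87, rise6_sd = 0.56
                          ),
                          noise_sd = c(glucose = 0.15, tg = 0.08),
                          sex_rise_shift = c(glyca = 0, il6 = 0),
                          age_range = c(18, 65),
                          male_fraction = 0.28,
                          bmi = c(mean = 25.6, sd = 5.0),
                          weight = c(mean = 72.9, sd = 15.3),
                          vfm = c(mean = 1.2, sd = 0.5),
                          microbiome_pc_sd = 0.12 * 0.85^(0:9)) {
  if (!is.numeric(n_participants) || n_participants < 2) {
    pp_stop("`n_participants` must be at least 2")
  }
  check_times <- function(tt, need, what) {
    if (any(diff(tt) <= 0)) pp_stop(sprintf("`%s` must be strictly increasing", what))
    miss <- setdiff(need, tt)
    if (length(miss) > 0) {
      pp_stop(sprintf("`%s` must include %s min", what, paste(miss, collapse = ", ")))
    }
  }
  check_times(sampling_times, c(0, 30, 60, 120, 240, 360), "sampling_times")
  check_times(tg_times, c(0, 240, 360), "tg_times")
  sds <- c(
    glucose_baseline["sd"], tg_baseline["sd"], glucose_peaks$amplitude_sd,
    tg_peak$amplitude_sd, noise_sd, glyca_scale[c("fasting_sd", "pp4_sd", "pp6_sd")],
    il6[c("fasting_sd", "rise4_sd", "rise6_sd")], bmi["sd"], weight["sd"],
    vfm["sd"], microbiome_pc_sd, glyca_noise_sd
  )
  if (any(sds < 0)) pp_stop("all standard deviations must be >= 0")
  if (any(glucose_peaks$width <= 0) || tg_peak$width <= 0) {
    pp_stop("peak widths must be strictly positive")
  }
  if (is.null(tg_peak$peak_time_sd)) tg_peak$peak_time_sd <- 0
  if (tg_peak$peak_time_sd < 0) pp_stop("`tg_peak$peak_time_sd` must be >= 0")
  if (!is.null(glyca_noise_sd)) glyca_noise_sd <- rep_len(glyca_noise_sd, 3)
  structure(
    list(
      n_participants = as.integer(n_participants), seed = as.integer(seed),
      sampling_times = sampling_times, tg_times = tg_times,
      glucose_baseline = glucose_baseline, glucose_peaks = glucose_peaks,
      tg_baseline = tg_baseline, tg_peak = tg_peak,
      effect_vfm_on_tg = effect_vfm_on_tg,
      effect_tg_on_glyca = effect_tg_on_glyca,
      effect_vfm_direct_on_glyca = effect_vfm_direct_on_glyca,
      effect_tg6_on_glyca6 = effect_tg6_on_glyca6,
      effect_glucose_on_glyca6 = effect_glucose_on_glyca6,
      effect_glyca0_on_glyca6 = effect_glyca0_on_glyca6,
      glyca_noise_sd = glyca_noise_sd, glyca_scale = glyca_scale, il6 = il6,
      noise_sd = noise_sd, sex_rise_shift = sex_rise_shift,
      age_range = age_range, male_fraction = male_fraction,
      bmi = bmi, weight = weight, vfm = vfm,
      microbiome_pc_sd = microbiome_pc_sd
    ),
    class = "cohort_config"
  )
}

# E[k] and E[k^2] of the Gaussian peak kernel k = exp(-d^2 / (2 w^2)) when
# the offset d ~ N(m, s): closed-form Gaussian convolution identities.
gaussian_kernel_moments <- function(m, s, w) {
  ek <- w / sqrt(w^2 + s^2) * exp(-m^2 / (2 * (w^2 + s^2)))
  w2 <- w / sqrt(2)
  ek2 <- w2 / sqrt(w2^2 + s^2) * exp(-m^2 / (2 * (w2^2 + s^2)))
  list(ek = ek, ek2 = ek2)
}

#' Simulate a postprandial cohort with planted structure
#'
#' Draws a complete synthetic cohort under the conditions in a
#' [cohort_config()]: covariates, glucose and TG concentration curves with
#' participant-level random amplitudes plus measurement noise, and GlycA /
#' IL-6 marker series at 0, 4 and 6 h. The GlycA series carries the planted
#' VFM -> fasting TG -> GlycA path structure; IL-6 rises are independent of
#' the metabolic curves. Latent standardized scores are formed from the
#' *realized* (truncated-at-zero) concentrations so that with all noise SDs
#' set to zero the marker values are exact linear functions of the observed
#' covariates and the planted slopes are recoverable exactly by regression.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_dataset`: a list with tibbles
#'   `curves` (participant_id, analyte, time_min, value), `markers`
#'   (participant_id, marker, time_h, value), `covariates` (age, sex, bmi,
#'   weight, vfm, pc1..pc10), the `truth` record of planted parameters and
#'   derived standardization constants, and the `config`.
#' @examples
#' dat <- simulate_cohort(cohort_config(n_participants = 50, seed = 7))
#' dplyr::count(dat$curves, analyte)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    pp_stop("`config` must be created with cohort_config()")
  }
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  pid <- sprintf("P%04d", seq_len(n))

  # covariates ---------------------------------------------------------------
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(runif(n) < cfg$male_fraction, "M", "F")
  bmi <- pmax(rnorm(n, cfg$bmi["mean"], cfg$bmi["sd"]), 15)
  weight <- pmax(rnorm(n, cfg$weight["mean"], cfg$weight["sd"]), 35)
  vfm <- pmax(rnorm(n, cfg$vfm["mean"], cfg$vfm["sd"]), 0.05)
  pcs <- vapply(cfg$microbiome_pc_sd, function(s) rnorm(n, 0, s), numeric(n))
  colnames(pcs) <- paste0("pc", seq_along(cfg$microbiome_pc_sd))

  # latent standardized covariate scores (from realized values)
  z_vfm <- (vfm - cfg$vfm["mean"]) / cfg$vfm["sd"]
  e_vt <- cfg$effect_vfm_on_tg
  z_tg_raw <- e_vt * z_vfm + sqrt(max(0, 1 - e_vt^2)) * rnorm(n)
  tg_base <- pmax(cfg$tg_baseline["mean"] + cfg$tg_baseline["sd"] * z_tg_raw, 0.1)

  # participant-level curve parameters ---------------------------------------
  gp <- cfg$glucose_peaks
  glu_base <- pmax(rnorm(n, cfg$glucose_baseline["mean"], cfg$glucose_baseline["sd"]), 3)
  glu_amp1 <- pmax(rnorm(n, gp$amplitude[1], gp$amplitude_sd[1]), 0.2)
  glu_amp2 <- pmax(rnorm(n, gp$amplitude[2], gp$amplitude_sd[2]), 0.2)
  tp <- cfg$tg_peak
  tg_amp <- pmax(rnorm(n, tp$amplitude, tp$amplitude_sd), 0.05)
  tg_pt <- rnorm(n, tp$peak_time, tp$peak_time_sd)

  # fasting TG as observed at t = 0 (baseline plus the tiny peak tail), so
  # the planted GlycA system is exactly linear in the emitted fasting value
  tg_fast <- tg_base + tg_amp * exp(-tg_pt^2 / (2 * tp$width^2))
  z_tg <- (tg_fast - cfg$tg_baseline["mean"]) / cfg$tg_baseline["sd"]

  # GlycA latent system -------------------------------------------------------
  e_tg <- cfg$effect_tg_on_glyca
  e_vd <- cfg$effect_vfm_direct_on_glyca
  c_g0 <- cfg$effect_glyca0_on_glyca6
  c_t6 <- cfg$effect_tg6_on_glyca6
  c_glu <- cfg$effect_glucose_on_glyca6

  # latent TG value at 360 min and first glucose peak amplitude, standardized
  # by their theoretical moments (closed-form Gaussian-convolution moments of
  # the peak kernel under the random peak time)
  km <- gaussian_kernel_moments(360 - tp$peak_time, tp$peak_time_sd, tp$width)
  k6_i <- exp(-(360 - tg_pt)^2 / (2 * tp$width^2))
  mu_t6 <- cfg$tg_baseline["mean"] + tp$amplitude * km$ek
  var_amp_k <- (tp$amplitude^2 + tp$amplitude_sd^2) * km$ek2 -
    (tp$amplitude * km$ek)^2
  sd_t6 <- sqrt(cfg$tg_baseline["sd"]^2 + var_amp_k)
  z_t6 <- (tg_base + tg_amp * k6_i - mu_t6) / sd_t6
  z_a1 <- (glu_amp1 - gp$amplitude[1]) / gp$amplitude_sd[1]

  rho_g0_t6 <- cfg$tg_baseline["sd"] * (e_tg + e_vd * e_vt) / sd_t6
  if (is.null(cfg$glyca_noise_sd)) {
    r0 <- sqrt(max(0, 1 - (e_tg^2 + e_vd^2 + 2 * e_tg * e_vd * e_vt)))
    sig6 <- c_g0^2 + c_t6^2 + c_glu^2 + 2 * c_g0 * c_t6 * rho_g0_t6
    r6 <- sqrt(max(0, 1 - sig6))
    r4 <- 0.25
    glyca_noise <- c(r0, r4, r6)
  } else {
    glyca_noise <- cfg$glyca_noise_sd
  }

  shift_g <- (sex == "M") * cfg$sex_rise_shift["glyca"]
  g0 <- e_tg * z_tg + e_vd * z_vfm + glyca_noise[1] * rnorm(n)
  g6 <- c_g0 * g0 + c_t6 * z_t6 + c_glu * z_a1 + glyca_noise[3] * rnorm(n) + shift_g
  g4 <- 0.5 * (g0 + g6) + glyca_noise[2] * rnorm(n)

  gs <- cfg$glyca_scale
  glyca_0h <- pmax(gs["fasting_mean"] + gs["fasting_sd"] * g0, 0.2)
  glyca_4h <- pmax(gs["pp4_mean"] + gs["pp4_sd"] * g4, 0.2)
  glyca_6h <- pmax(gs["pp6_mean"] + gs["pp6_sd"] * g6, 0.2)

  # IL-6: meal-independent rises ---------------------------------------------
  il <- cfg$il6
  shift_i <- (sex == "M") * cfg$sex_rise_shift["il6"] * il["rise6_sd"]
  il6_0h <- pmax(rnorm(n, il["fasting_mean"], il["fasting_sd"]), 0.01)
  il6_4h <- pmax(il6_0h + rnorm(n, il["rise4_mean"], il["rise4_sd"]), 0.01)
  il6_6h <- pmax(il6_0h + rnorm(n, il["rise6_mean"], il["rise6_sd"]) + shift_i, 0.01)

  # curves --------------------------------------------------------------------
  glu_t <- cfg$sampling_times
  tg_t <- cfg$tg_times
  glu_mat <- t(vapply(seq_len(n), function(i) {
    curve_model(glu_t, c(glu_amp1[i], glu_amp2[i]), gp$peak_time, gp$width, glu_base[i])
  }, numeric(length(glu_t))))
  tg_mat <- t(vapply(seq_len(n), function(i) {
    curve_model(tg_t, tg_amp[i], tg_pt[i], tp$width, tg_base[i])
  }, numeric(length(tg_t))))
  glu_mat <- pmax(glu_mat + rnorm(length(glu_mat), 0, cfg$noise_sd["glucose"]), 0.1)
  tg_mat <- pmax(tg_mat + rnorm(length(tg_mat), 0, cfg$noise_sd["tg"]), 0.01)

  curves <- dplyr::bind_rows(
    tibble::tibble(
      participant_id = rep(pid, each = length(glu_t)),
      analyte = "glucose",
      time_min = rep(glu_t, times = n),
      value = as.vector(t(glu_mat))
    ),
    tibble::tibble(
      participant_id = rep(pid, each = length(tg_t)),
      analyte = "TG",
      time_min = rep(tg_t, times = n),
      value = as.vector(t(tg_mat))
    )
  )

  markers <- tidyr::pivot_longer(
    tibble::tibble(
      participant_id = pid,
      `GlycA.0` = glyca_0h, `GlycA.4` = glyca_4h, `GlycA.6` = glyca_6h,
      `IL-6.0` = il6_0h, `IL-6.4` = il6_4h, `IL-6.6` = il6_6h
    ),
    -"participant_id",
    names_to = c("marker", "time_h"), names_sep = "\\.",
    values_to = "value"
  )
  markers$time_h <- as.numeric(markers$time_h)

  covariates <- tibble::tibble(
    participant_id = pid, age = age, sex = sex, bmi = bmi,
    weight = weight, vfm = vfm
  )
  covariates <- dplyr::bind_cols(covariates, tibble::as_tibble(pcs))

  truth <- list(
    effect_vfm_on_tg = e_vt, effect_tg_on_glyca = e_tg,
    effect_vfm_direct_on_glyca = e_vd,
    effect_tg6_on_glyca6 = c_t6, effect_glucose_on_glyca6 = c_glu,
    effect_glyca0_on_glyca6 = c_g0,
    glyca_noise_sd = glyca_noise,
    glyca_scale = gs, il6 = il,
    tg_baseline = cfg$tg_baseline, glucose_baseline = cfg$glucose_baseline,
    glucose_peaks = gp, tg_peak = tp,
    vfm = cfg$vfm, noise_sd = cfg$noise_sd,
    k6_mean = km$ek, k6_sq_mean = km$ek2,
    mu_t6 = unname(mu_t6), sd_t6 = unname(sd_t6),
    rho_g0_t6 = unname(rho_g0_t6),
    sex_rise_shift = cfg$sex_rise_shift,
    seed = cfg$seed
  )

  structure(
    list(
      curves = curves, markers = markers, covariates = covariates,
      truth = truth, config = cfg
    ),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n <- nrow(x$covariates)
  cat(sprintf(
    "<cohort_dataset> %d participants, %d curve samples, %d marker values (seed %d)\n",
    n, nrow(x$curves), nrow(x$markers), x$truth$seed
  ))
  invisible(x)
}

#' Plot cohort-mean postprandial curves
#'
#' Mean concentration (with a +/- 1 SD ribbon) per analyte across the
#' sampling grid; the glucose panel shows the two meal peaks and the TG
#' panel the late single peak.
#'
#' @param object A `cohort_dataset` from [simulate_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_dataset <- function(object, ...) {
  summ <- object$curves |>
    dplyr::group_by(.data$analyte, .data$time_min) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_min, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(
      x = "Time after breakfast (min)", y = "Concentration (mmol/L)",
      title = "Cohort-mean postprandial curves"
    )
}
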