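# Two-sample Mendelian-randomization estimators and diagnostics on
# harmonized GWAS summary statistics. Instruments are assumed independent
# (no LD clumping is performed).

sumstat_cols <- c(
  "snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n"
)

check_harmonized <- function(h, min_snp = 1) {
  check_columns(
    h, c("snp", "beta_exp", "se_exp", "beta_out", "se_out"), "harmonized data"
  )
  if (nrow(h) < min_snp) {
    pp_stop(sprintf("need at least %d harmonized instrument(s)", min_snp))
  }
  if (any(h$se_exp <= 0) || any(h$se_out <= 0)) {
    pp_stop("standard errors must be strictly positive")
  }
  invisible(h)
}

mr_row <- function(method, beta, se, p, n_snp, model = NA_character_) {
  tibble::tibble(
    method = method, beta = beta, se = se, p = p,
    n_snp = as.integer(n_snp), model = model
  )
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two association tables on SNP id and aligns the outcome
#' effects to the exposure's effect allele: when the allele pair is swapped
#' the outcome beta sign is flipped (and its EAF reflected); incompatible
#' allele pairs are dropped with a warning. Strand-ambiguous palindromic
#' SNPs (A/T or C/G) whose exposure EAF falls inside `palindromic_window`
#' are excluded; palindromic SNPs outside the window are kept and flagged.
#' Every action is recorded in the `"log"` attribute.
#'
#' @param exposure,outcome Summary-statistic tibbles with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param palindromic_window EAF interval within which palindromic SNPs
#'   are considered unresolvable; default `c(0.42, 0.58)`.
#' @return A tibble of class `mr_harmonized` with columns `snp`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `action`
#'   (`"match"`/`"flip"`), `palindromic`; attribute `log` is a tibble of
#'   per-SNP actions including drops.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  check_columns(exposure, sumstat_cols, "exposure")
  check_columns(outcome, sumstat_cols, "outcome")
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) pp_stop("no shared SNPs between exposure and outcome")

  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  pal <- (ex$effect_allele == "A" & ex$other_allele == "T") |
    (ex$effect_allele == "T" & ex$other_allele == "A") |
    (ex$effect_allele == "C" & ex$other_allele == "G") |
    (ex$effect_allele == "G" & ex$other_allele == "C")
  ambiguous <- pal & ex$eaf >= palindromic_window[1] & ex$eaf <= palindromic_window[2]
  incompatible <- !same & !swap

  action <- dplyr::case_when(
    incompatible ~ "drop_incompatible",
    ambiguous ~ "drop_palindromic",
    swap ~ "flip",
    TRUE ~ "match"
  )
  log <- tibble::tibble(
    snp = shared, action = action, palindromic = pal, eaf_exposure = ex$eaf
  )
  if (any(incompatible)) {
    warning(sprintf(
      "dropped %d SNP(s) with incompatible allele pairs: %s",
      sum(incompatible), paste(shared[incompatible], collapse = ", ")
    ), call. = FALSE)
  }
  keep <- !incompatible & !ambiguous
  if (!any(keep)) pp_stop("no instruments remain after harmonization")

  beta_out <- ifelse(swap, -ou$beta, ou$beta)
  out <- tibble::tibble(
    snp = shared, beta_exp = ex$beta, se_exp = ex$se,
    beta_out = beta_out, se_out = ou$se, eaf = ex$eaf,
    action = action, palindromic = pal
  )[keep, ]
  attr(out, "log") <- log
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate `beta_out / beta_exp` with the
#' first-order standard error `se_out / |beta_exp|`, or the second-order
#' form `sqrt(se_out^2 / beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`
#' which also propagates the exposure uncertainty.
#'
#' @param h Harmonized instruments from [harmonize()] (or any tibble with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param se_order `"first"` (default) or `"second"`.
#' @return A tibble with one row per SNP: `snp`, `beta`, `se`, `p`.
#' @export
wald_ratio <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  check_harmonized(h)
  if (any(h$beta_exp == 0)) {
    pp_stop("weak instrument: `beta_exp` of 0 gives an undefined Wald ratio")
  }
  beta <- h$beta_out / h$beta_exp
  se <- if (se_order == "first") {
    h$se_out / abs(h$beta_exp)
  } else {
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  }
  tibble::tibble(
    snp = h$snp, beta = beta, se = se, p = 2 * pnorm(-abs(beta / se))
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of the outcome associations on the exposure
#' associations through the origin with weights `1 / se_out^2`
#' (equivalently the `gamma^2 / se_out^2`-weighted average of Wald
#' ratios). The fixed-effect SE is `(sum w)^(-1/2)`; the
#' multiplicative-random-effects model inflates it by
#' `max(1, sqrt(Q / (J - 1)))`. A single instrument degrades to the Wald
#' ratio.
#'
#' @param h Harmonized instruments from [harmonize()].
#' @param model `"random"` (default) or `"fixed"`.
#' @return A one-row tibble: `method`, `beta`, `se`, `p`, `n_snp`, `model`.
#' @export
ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(h, 1)
  J <- nrow(h)
  w <- 1 / h$se_out^2
  sw <- sum(w * h$beta_exp^2)
  if (sw == 0) pp_stop("degenerate instruments: all IVW weights are zero")
  beta <- sum(w * h$beta_exp * h$beta_out) / sw
  se <- sqrt(1 / sw)
  if (J > 1 && model == "random") {
    Q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  mr_row("ivw", beta, se, 2 * pnorm(-abs(beta / se)), J, model)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with a free intercept (weights `1 / se_out^2`), after
#' orienting every instrument to a positive exposure effect. The slope is
#' the causal estimate; the intercept estimates average directional
#' pleiotropy and its p-value is the pleiotropy test. Standard errors use
#' the multiplicative random-effects convention (residual SD floored at 1)
#' and t-based p-values on J - 2 df. With `intercept = FALSE` the fit
#' reduces exactly to the fixed-effect IVW estimate.
#'
#' @param h Harmonized instruments (J >= 3).
#' @param intercept Keep the pleiotropy intercept (default `TRUE`).
#' @return A tibble with rows `egger` (slope) and `egger_intercept`, or a
#'   single `egger_no_intercept` row when `intercept = FALSE`.
#' @export
mr_egger <- function(h, intercept = TRUE) {
  check_harmonized(h, 3)
  s <- ifelse(h$beta_exp < 0, -1, 1)
  bx <- h$beta_exp * s
  by <- h$beta_out * s
  w <- 1 / h$se_out^2
  J <- nrow(h)
  if (!intercept) {
    fit <- lm(by ~ bx - 1, weights = w)
    beta <- unname(coef(fit)[1])
    se <- sqrt(1 / sum(w * bx^2)) # fixed-effect scale: exact IVW equivalence
    return(mr_row(
      "egger_no_intercept", beta, se, 2 * pnorm(-abs(beta / se)), J, "fixed"
    ))
  }
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  ses <- sm$coefficients[, "Std. Error"] / min(sm$sigma, 1)
  est <- coef(fit)
  p <- 2 * pt(-abs(est / ses), df = J - 2)
  dplyr::bind_rows(
    mr_row("egger", unname(est["bx"]), unname(ses["bx"]),
           unname(p["bx"]), J, "random"),
    mr_row("egger_intercept", unname(est["(Intercept)"]),
           unname(ses["(Intercept)"]), unname(p["(Intercept)"]), J, "random")
  )
}

#' Cochran's Q heterogeneity test
#'
#' Heterogeneity of the per-SNP causal estimates about the IVW fit
#' (Cochran's Q, J - 1 df) or about the Egger fit (Rucker's Q', J - 2 df),
#' with an upper-tail chi-square p-value.
#'
#' @param h Harmonized instruments (J >= 2 for IVW, >= 4 for Egger).
#' @param method `"ivw"` (default) or `"egger"`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  check_harmonized(h, if (method == "ivw") 2 else 4)
  w <- 1 / h$se_out^2
  J <- nrow(h)
  if (method == "ivw") {
    b <- ivw(h, "fixed")$beta
    Q <- sum(w * (h$beta_out - b * h$beta_exp)^2)
    df <- J - 1
  } else {
    eg <- mr_egger(h)
    s <- ifelse(h$beta_exp < 0, -1, 1)
    resid <- h$beta_out * s -
      (eg$beta[eg$method == "egger_intercept"] +
         eg$beta[eg$method == "egger"] * h$beta_exp * s)
    Q <- sum(w * resid^2)
    df <- J - 2
  }
  tibble::tibble(
    method = method, statistic = Q, df = df,
    p_value = pchisq(Q, df, lower.tail = FALSE)
  )
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn and flags any
#' exclusion that changes the sign of the estimate or moves it by more
#' than one full-sample fixed-effect standard error (the fixed-effect
#' yardstick is used for flagging because the multiplicative
#' random-effects SE is itself inflated by the outlier under test).
#'
#' @param h Harmonized instruments (J >= 3).
#' @param model IVW model passed to [ivw()].
#' @return A tibble with one row per excluded SNP: `snp`, `beta`, `se`,
#'   `p`, `influential`; the full-sample estimate is in attribute `full`.
#' @export
leave_one_out <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(h, 3)
  full <- ivw(h, model)
  full_fixed_se <- ivw(h, "fixed")$se
  out <- purrr::map_dfr(seq_len(nrow(h)), function(j) {
    e <- ivw(h[-j, ], model)
    tibble::tibble(snp = h$snp[j], beta = e$beta, se = e$se, p = e$p)
  })
  out$influential <- sign(out$beta) != sign(full$beta) |
    abs(out$beta - full$beta) > full_fixed_se
  attr(out, "full") <- full
  out
}

#' Instrument-strength F statistics
#'
#' Per-SNP `F = (beta / se)^2` of the exposure associations, with the
#' count exceeding the conventional strong-instrument threshold of 20.
#'
#' @param x Either an exposure summary-statistic tibble (`beta`, `se`) or
#'   harmonized instruments (`beta_exp`, `se_exp`).
#' @param threshold Strong-instrument threshold, default 20.
#' @return A list of class `instrument_strength`: `per_snp` tibble
#'   (`snp`, `f`), `min_f`, `mean_f`, `n_strong`, `threshold`.
#' @export
instrument_strength <- function(x, threshold = 20) {
  if (all(c("beta_exp", "se_exp") %in% names(x))) {
    beta <- x$beta_exp
    se <- x$se_exp
  } else {
    check_columns(x, c("beta", "se"), "exposure statistics")
    beta <- x$beta
    se <- x$se
  }
  if (any(se <= 0)) pp_stop("standard errors must be strictly positive")
  f <- (beta / se)^2
  structure(
    list(
      per_snp = tibble::tibble(snp = x$snp, f = f),
      min_f = min(f), mean_f = mean(f),
      n_strong = sum(f > threshold), threshold = threshold
    ),
    class = "instrument_strength"
  )
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf(
    "<instrument_strength> %d SNPs: mean F = %.1f, min F = %.1f, %d with F > %g\n",
    nrow(x$per_snp), x$mean_f, x$min_f, x$n_strong, x$threshold
  ))
  invisible(x)
}

#' @export
tidy.instrument_strength <- function(x, ...) x$per_snp

#' @export
glance.instrument_strength <- function(x, ...) {
  tibble::tibble(
    mean_f = x$mean_f, min_f = x$min_f, n_strong = x$n_strong,
    threshold = x$threshold, n_snp = nrow(x$per_snp)
  )
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed weighted residual sum of squares about the
#' leave-one-out IVW expectations,
#' `RSS = sum_j (beta_out_j - beta_(-j) beta_exp_j)^2 / se_out_j^2`, is
#' compared against its parametric null distribution obtained by
#' simulating complete two-sample datasets under the no-pleiotropy model
#' -- exposure associations `~ N(beta_exp_j, se_exp_j)` and outcome
#' associations `~ N(beta_(-j) beta_exp_j, se_out_j)` -- and recomputing
#' the leave-one-out RSS for each simulated dataset. Simulating both
#' sides keeps the global test calibrated when exposure estimates carry
#' sampling noise.
#' Per-SNP outlier p-values use the analogous comparison of each SNP's
#' weighted residual, Bonferroni-corrected; SNPs below `outlier_alpha`
#' after correction are flagged. When outliers are found, the distortion
#' test compares the relative change in the IVW estimate after removing
#' them against the distribution obtained by removing equally many
#' randomly chosen SNPs.
#'
#' @param h Harmonized instruments (J >= 4).
#' @param n_sim Number of parametric simulations (>= 100, default 1000).
#' @param seed Integer seed; the report is deterministic given the seed.
#' @param outlier_alpha Bonferroni-corrected flagging threshold (0.05).
#' @param n_perm Random removals for the distortion test (default 1000).
#' @return A list of class `mr_presso`: `rss_obs`, `global_p`, `per_snp`
#'   tibble (`snp`, `p_raw`, `p_bonferroni`, `outlier`), `outliers`,
#'   `beta_all`, `beta_outlier_corrected`, `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_alpha = 0.05,
                      n_perm = 1000) {
  check_harmonized(h, 4)
  if (n_sim < 100) pp_stop("`n_sim` must be at least 100")
  set.seed(seed)
  J <- nrow(h)
  bx <- h$beta_exp
  by <- h$beta_out
  w <- 1 / h$se_out^2
  S1 <- sum(w * bx * by)
  S2 <- sum(w * bx^2)
  beta_loo <- (S1 - w * bx * by) / (S2 - w * bx^2)
  expected <- beta_loo * bx
  res2_obs <- w * (by - expected)^2
  rss_obs <- sum(res2_obs)

  BX <- matrix(rnorm(J * n_sim, mean = bx, sd = h$se_exp), nrow = J)
  BY <- matrix(rnorm(J * n_sim, mean = expected, sd = h$se_out), nrow = J)
  S1s <- colSums(w * BX * BY)
  S2s <- colSums(w * BX^2)
  # leave-one-out slope per SNP and simulation
  BLOO <- (sweep(-(w * BX) * BY, 2, S1s, "+")) /
    (sweep(-(w * BX) * BX, 2, S2s, "+"))
  R2 <- w * (BY - BLOO * BX)^2
  RSSs <- colSums(R2)
  global_p <- (1 + sum(RSSs >= rss_obs)) / (1 + n_sim)

  p_raw <- (1 + rowSums(R2 >= res2_obs)) / (1 + n_sim)
  p_bonf <- pmin(p_raw * J, 1)
  outlier <- p_bonf < outlier_alpha
  per_snp <- tibble::tibble(
    snp = h$snp, p_raw = p_raw, p_bonferroni = p_bonf, outlier = outlier
  )

  beta_all <- ivw(h, "fixed")$beta
  beta_corr <- NA_real_
  distortion_p <- NA_real_
  if (any(outlier)) {
    keep <- !outlier
    if (sum(keep) >= 1) {
      beta_corr <- ivw(h[keep, ], "fixed")$beta
      d_obs <- (beta_corr - beta_all) / abs(beta_all)
      n_out <- sum(outlier)
      pool <- which(keep)
      d_sim <- vapply(seq_len(n_perm), function(b) {
        drop <- sample(pool, n_out, replace = TRUE)
        bb <- ivw(h[-unique(drop), , drop = FALSE], "fixed")$beta
        (bb - beta_all) / abs(beta_all)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_perm)
    }
  }
  structure(
    list(
      rss_obs = rss_obs, global_p = global_p, per_snp = per_snp,
      outliers = h$snp[outlier], beta_all = beta_all,
      beta_outlier_corrected = beta_corr, distortion_p = distortion_p,
      n_sim = n_sim, seed = seed
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf(
    "<mr_presso> global RSS = %.2f, p = %.4g; %d outlier(s)%s\n",
    x$rss_obs, x$global_p, length(x$outliers),
    if (length(x$outliers) > 0) {
      sprintf(" (%s), distortion p = %.3g",
              paste(x$outliers, collapse = ", "), x$distortion_p)
    } else ""
  ))
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) x$per_snp

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    rss_obs = x$rss_obs, global_p = x$global_p,
    n_outliers = length(x$outliers), beta_all = x$beta_all,
    beta_outlier_corrected = x$beta_outlier_corrected,
    distortion_p = x$distortion_p, n_sim = x$n_sim
  )
}

#' MR robust adjusted profile score (MR-RAPS)
#'
#' Solves the profile-score estimating equation
#' `sum_j psi(t_j(beta)) dt_j/dbeta = 0` with standardized residuals
#' `t_j(beta) = (beta_out_j - beta beta_exp_j) /
#' sqrt(se_out_j^2 + beta^2 se_exp_j^2 + tau2)`. The plain score uses
#' `psi(t) = t`; the Huber score caps at `k_huber`. With
#' `overdispersion = TRUE` the pleiotropy variance `tau2` solves the
#' companion moment equation `sum_j (psi(t_j) t_j - delta) = 0` (floored
#' at zero), iterating with the beta equation. The standard error is a
#' sandwich estimate. With exact exposure effects and `tau2 = 0` the
#' score reduces to the fixed-effect IVW normal equations.
#'
#' @param h Harmonized instruments (J >= 3).
#' @param overdispersion Estimate a pleiotropy variance `tau2`
#'   (default `FALSE`).
#' @param loss `"plain"` (default) or `"huber"`.
#' @param k_huber Huber tuning constant (1.345).
#' @param max_iter,tol Iteration controls for the beta / tau2 alternation.
#' @return A one-row tibble (`method = "raps"`, `beta`, `se`, `p`,
#'   `n_snp`, `model`) with the estimated `tau2` as an attribute.
#' @export
mr_raps <- function(h, overdispersion = FALSE, loss = c("plain", "huber"),
                    k_huber = 1.345, max_iter = 100, tol = 1e-10) {
  loss <- match.arg(loss)
  check_harmonized(h, 3)
  bx <- h$beta_exp
  by <- h$beta_out
  sx2 <- h$se_exp^2
  sy2 <- h$se_out^2
  psi <- if (loss == "plain") {
    function(t) t
  } else {
    function(t) pmax(pmin(t, k_huber), -k_huber)
  }
  psi_prime <- if (loss == "plain") {
    function(t) rep(1, length(t))
  } else {
    function(t) as.numeric(abs(t) < k_huber)
  }
  delta <- if (loss == "plain") 1 else 2 * pnorm(k_huber) - 1

  tvals <- function(beta, tau2) {
    s <- sqrt(sy2 + beta^2 * sx2 + tau2)
    list(t = (by - beta * bx) / s, s = s)
  }
  score <- function(beta, tau2) {
    tv <- tvals(beta, tau2)
    dt <- -(bx / tv$s) - tv$t * beta * sx2 / tv$s^2
    sum(psi(tv$t) * dt)
  }
  # psi = d rho / dt, so the estimating equation is the stationarity
  # condition of the profile objective R(beta) = sum rho(t_j(beta));
  # minimizing R on an expanding bracket is robust because the score
  # vanishes at +/- infinity and simple bracket expansion can fail.
  rho <- if (loss == "plain") {
    function(t) t^2 / 2
  } else {
    function(t) ifelse(abs(t) <= k_huber, t^2 / 2,
                       k_huber * abs(t) - k_huber^2 / 2)
  }
  objective <- function(beta, tau2) {
    tv <- tvals(beta, tau2)
    sum(rho(tv$t))
  }
  solve_beta <- function(tau2, b0, se0) {
    half <- 10 * max(se0, 1e-8)
    for (i in 1:20) {
      opt <- stats::optimize(objective, c(b0 - half, b0 + half), tau2 = tau2,
                             tol = 1e-12)
      inner <- abs(opt$minimum - b0) < 0.99 * half
      if (inner) return(opt$minimum)
      half <- half * 4
    }
    pp_stop("MR-RAPS did not converge: no interior profile-score minimum found")
  }
  moment <- function(tau2, beta) {
    tv <- tvals(beta, tau2)
    sum(psi(tv$t) * tv$t - delta)
  }

  init <- ivw(h, "fixed")
  beta <- init$beta
  tau2 <- 0
  for (it in seq_len(max_iter)) {
    beta_new <- solve_beta(tau2, beta, init$se)
    tau2_new <- tau2
    if (overdispersion) {
      if (moment(0, beta_new) <= 0) {
        tau2_new <- 0
      } else {
        hi <- max(sy2) # expand until the moment turns negative
        while (moment(hi, beta_new) > 0 && hi < 1e6) hi <- hi * 4
        tau2_new <- uniroot(moment, c(0, hi), beta = beta_new, tol = 1e-12)$root
      }
    }
    done <- abs(beta_new - beta) < tol && abs(tau2_new - tau2) < tol
    beta <- beta_new
    tau2 <- tau2_new
    if (done) break
  }

  tv <- tvals(beta, tau2)
  dt <- -(bx / tv$s) - tv$t * beta * sx2 / tv$s^2
  A <- sum(psi_prime(tv$t) * dt^2)
  B <- sum(psi(tv$t)^2 * dt^2)
  se <- sqrt(B) / abs(A)
  out <- mr_row(
    "raps", beta, se, 2 * pnorm(-abs(beta / se)), nrow(h),
    if (overdispersion) "overdispersed" else "simple"
  )
  attr(out, "tau2") <- tau2
  out
}

#' Run the full MR method panel
#'
#' Convenience wrapper returning IVW, MR-Egger (slope and intercept),
#' MR-RAPS and per-method heterogeneity in one tidy table.
#'
#' @param h Harmonized instruments (J >= 4 recommended).
#' @param model IVW model.
#' @return A tibble of estimates with attribute `heterogeneity` (the
#'   [cochran_q()] rows for IVW and Egger).
#' @export
mr_all <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  out <- dplyr::bind_rows(ivw(h, model), mr_egger(h), mr_raps(h))
  attr(out, "heterogeneity") <- dplyr::bind_rows(
    cochran_q(h, "ivw"),
    if (nrow(h) >= 4) cochran_q(h, "egger")
  )
  out
}

#' Scatter plot of harmonized instruments with fitted MR slopes
#'
#' @param h Harmonized instruments from [harmonize()].
#' @param model IVW model for the fitted line.
#' @return A ggplot of outcome vs exposure associations with +/- 1 SE
#'   error bars, the IVW line through the origin and the Egger line.
#' @export
plot_mr <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(h, 3)
  s <- ifelse(h$beta_exp < 0, -1, 1)
  d <- tibble::tibble(
    bx = h$beta_exp * s, by = h$beta_out * s,
    se_x = h$se_exp, se_y = h$se_out
  )
  iv <- ivw(h, model)
  eg <- mr_egger(h)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$by - .data$se_y, ymax = .data$by + .data$se_y
    ), width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$bx - .data$se_x, xmax = .data$bx + .data$se_x
    ), height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = iv$beta, intercept = 0, colour = "steelblue") +
    ggplot2::geom_abline(
      slope = eg$beta[eg$method == "egger"],
      intercept = eg$beta[eg$method == "egger_intercept"],
      colour = "firebrick", linetype = 2
    ) +
    ggplot2::labs(
      x = "SNP effect on exposure", y = "SNP effect on outcome",
      title = sprintf(
        "IVW slope %.3f (blue), Egger slope %.3f (red, dashed)",
        iv$beta, eg$beta[eg$method == "egger"]
      )
    )
}
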