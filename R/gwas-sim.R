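#' Configuration for synthetic two-sample GWAS summary statistics
#'
#' Conditions for [simulate_gwas()]: independent SNP instruments with allele
#' frequencies Uniform(0.05, 0.95), per-allele effects on a standardized
#' exposure, and outcome effects equal to `causal_beta` times the true
#' instrument effect plus optional pleiotropy and designated outliers.
#' Standard errors follow the usual `1/sqrt(2 p (1 - p) n)` form for a
#' standardized trait.
#'
#' @param n_snps Number of instruments J (>= 1; >= 3 for the multi-SNP
#'   estimators downstream).
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and
#'   outcome associations.
#' @param causal_beta Planted causal effect per SD of exposure.
#' @param mean_f Target expected instrument F statistic: per-SNP
#'   noncentralities are drawn `lambda_j^2 = Uniform(0.5, 1.5) * mean_f - 1`
#'   and true effects set to `gamma_j = +/- lambda_j * se_j` (random sign),
#'   so `E[(gamma_hat/se)^2]` equals `mean_f` and every instrument is
#'   strong, emulating a genome-wide-significant instrument set.
#' @param pleiotropy_mean,pleiotropy_sd Direct (horizontal) SNP-outcome
#'   effects `~ N(mean, sd)`, oriented relative to the exposure-increasing
#'   allele (so a nonzero mean is directional pleiotropy as seen by an
#'   Egger regression of oriented instruments).
#' @param n_outliers Number of SNPs given an extra outcome displacement.
#' @param outlier_effect Displacement magnitude in units of the SNP's
#'   outcome SE (e.g. 10 plants a 10-sigma outlier).
#' @param palindromic_fraction Fraction of SNPs emitted with
#'   strand-ambiguous (A/T or C/G) allele pairs, for harmonization tests.
#' @param seed Integer seed.
#' @return An object of class `gwas_config`.
#' @export
gwas_config <- function(n_snps = 50,
                        n_exposure = 500000,
                        n_outcome = 60000,
                        causal_beta = 0.5,
                        mean_f = 200,
                        pleiotropy_mean = 0,
                        pleiotropy_sd = 0,
                        n_outliers = 0,
                        outlier_effect = 0,
                        palindromic_fraction = 0,
                        seed = 1L) {
  if (!is.numeric(n_snps) || n_snps < 1) pp_stop("`n_snps` must be >= 1")
  if (mean_f < 1) pp_stop("`mean_f` must be >= 1")
  if (pleiotropy_sd < 0) pp_stop("`pleiotropy_sd` must be >= 0")
  if (n_outliers < 0 || n_outliers > n_snps) {
    pp_stop("`n_outliers` must be between 0 and `n_snps`")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), n_exposure = n_exposure,
      n_outcome = n_outcome, causal_beta = causal_beta, mean_f = mean_f,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      n_outliers = as.integer(n_outliers), outlier_effect = outlier_effect,
      palindromic_fraction = palindromic_fraction, seed = as.integer(seed)
    ),
    class = "gwas_config"
  )
}

# True instrument effects with expected F statistic `mean_f`: per-SNP
# noncentrality spread Uniform(0.5, 1.5) * mean_f, random sign.
draw_instrument_effects <- function(J, mean_f, se) {
  f_nc <- runif(J, 0.5, 1.5) * mean_f
  sample(c(-1, 1), J, replace = TRUE) * se * sqrt(pmax(f_nc - 1, 0))
}

# Draw allele pairs; palindromic pairs (A/T, C/G) only where requested.
draw_alleles <- function(J, palindromic_fraction) {
  pairs <- list(
    c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"),
    c("G", "A"), c("C", "A"), c("T", "G"), c("T", "C")
  )
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- runif(J) < palindromic_fraction
  pick <- function(flag) {
    if (flag) pal_pairs[[sample.int(4, 1)]] else pairs[[sample.int(8, 1)]]
  }
  al <- t(vapply(is_pal, pick, character(2)))
  list(effect = al[, 1], other = al[, 2])
}

#' Simulate two-sample GWAS summary statistics with planted effects
#'
#' @param config A [gwas_config()].
#' @return An object of class `gwas_dataset`: a list with `exposure` and
#'   `outcome` summary-statistic tibbles (columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) and a `truth` record
#'   with the true per-SNP effects and outlier ids.
#' @examples
#' gw <- simulate_gwas(gwas_config(n_snps = 10, seed = 3))
#' head(gw$exposure)
#' @export
simulate_gwas <- function(config = gwas_config()) {
  if (!inherits(config, "gwas_config")) {
    pp_stop("`config` must be created with gwas_config()")
  }
  set.seed(config$seed)
  J <- config$n_snps
  snp <- sprintf("rs%06d", sample.int(999999, J))
  eaf <- runif(J, 0.05, 0.95)
  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
  se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)
  gamma <- draw_instrument_effects(J, config$mean_f, se_exp)
  # directional pleiotropy is defined relative to the exposure-raising allele
  pleio <- sign(gamma) * rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
  outlier_idx <- if (config$n_outliers > 0) {
    sample.int(J, config$n_outliers)
  } else {
    integer(0)
  }
  Gamma <- config$causal_beta * gamma + pleio
  Gamma[outlier_idx] <- Gamma[outlier_idx] +
    config$outlier_effect * se_out[outlier_idx]
  beta_exp <- gamma + rnorm(J, 0, se_exp)
  beta_out <- Gamma + rnorm(J, 0, se_out)
  al <- draw_alleles(J, config$palindromic_fraction)

  mk <- function(beta, se, n) {
    tibble::tibble(
      snp = snp, effect_allele = al$effect, other_allele = al$other,
      eaf = eaf, beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)), n = n
    )
  }
  structure(
    list(
      exposure = mk(beta_exp, se_exp, config$n_exposure),
      outcome = mk(beta_out, se_out, config$n_outcome),
      truth = list(
        gamma = gamma, Gamma = Gamma, pleiotropy = pleio,
        outlier_snps = snp[outlier_idx], causal_beta = config$causal_beta,
        seed = config$seed
      )
    ),
    class = "gwas_dataset"
  )
}

#' Configuration for a network-MR (mediation) GWAS triplet
#'
#' Conditions for [simulate_network_gwas()]: two disjoint instrument sets
#' (one for the exposure, one for the mediator) each measured against the
#' exposure, the mediator and the outcome, under the chain
#' exposure -> mediator -> outcome with an additional direct
#' exposure -> outcome path. Defaults plant the visceral-fat / fasting-TG /
#' GlycA regime: `alpha = 0.127` (exposure on mediator), `beta_med = 0.494`
#' (mediator on outcome) and total effect `gamma_total = 0.217`, so the
#' mediated proportion is `alpha * beta_med / gamma_total` (about 0.29).
#' The mediator has no effect on the exposure (reverse-null).
#'
#' @param n_snps_exposure,n_snps_mediator Instrument counts per set.
#' @param alpha,beta_med,gamma_total Planted standardized effects; the
#'   direct exposure -> outcome effect is `gamma_total - alpha * beta_med`.
#' @param n_sample GWAS sample size used for every association set.
#' @param mean_f Target expected instrument F statistic (see [gwas_config()]).
#' @param seed Integer seed.
#' @return An object of class `network_gwas_config`.
#' @export
network_gwas_config <- function(n_snps_exposure = 50,
                                n_snps_mediator = 50,
                                alpha = 0.127,
                                beta_med = 0.494,
                                gamma_total = 0.217,
                                n_sample = 60000,
                                mean_f = 200,
                                seed = 1L) {
  structure(
    list(
      n_snps_exposure = as.integer(n_snps_exposure),
      n_snps_mediator = as.integer(n_snps_mediator),
      alpha = alpha, beta_med = beta_med, gamma_total = gamma_total,
      n_sample = n_sample, mean_f = mean_f, seed = as.integer(seed)
    ),
    class = "network_gwas_config"
  )
}

#' Simulate GWAS summary statistics for a mediation chain
#'
#' @param config A [network_gwas_config()].
#' @return An object of class `network_gwas_dataset`: a list with six
#'   summary-statistic tibbles -- `exp_exposure`, `exp_mediator`,
#'   `exp_outcome` (the exposure's instruments against each trait) and
#'   `med_mediator`, `med_exposure`, `med_outcome` (the mediator's
#'   instruments) -- plus a `truth` record.
#' @seealso [run_network_mr()]
#' @export
simulate_network_gwas <- function(config = network_gwas_config()) {
  if (!inherits(config, "network_gwas_config")) {
    pp_stop("`config` must be created with network_gwas_config()")
  }
  set.seed(config$seed)
  direct <- config$gamma_total - config$alpha * config$beta_med

  one_set <- function(J, prefix, true_mult) {
    snp <- sprintf("%s%06d", prefix, sample.int(999999, J))
    eaf <- runif(J, 0.05, 0.95)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_sample)
    gamma <- draw_instrument_effects(J, config$mean_f, se)
    al <- draw_alleles(J, 0)
    mk <- function(mult) {
      beta <- mult * gamma + rnorm(J, 0, se)
      tibble::tibble(
        snp = snp, effect_allele = al$effect, other_allele = al$other,
        eaf = eaf, beta = beta, se = se,
        pval = 2 * pnorm(-abs(beta / se)), n = config$n_sample
      )
    }
    lapply(true_mult, mk)
  }

  # exposure instruments: effect 1 on exposure, alpha on mediator,
  # (direct + alpha * beta) on outcome
  exp_tabs <- one_set(
    config$n_snps_exposure, "rx",
    list(exposure = 1, mediator = config$alpha, outcome = config$gamma_total)
  )
  # mediator instruments: 0 on exposure (reverse-null), 1 on mediator,
  # beta on outcome
  med_tabs <- one_set(
    config$n_snps_mediator, "rm",
    list(mediator = 1, exposure = 0, outcome = config$beta_med)
  )

  structure(
    list(
      exp_exposure = exp_tabs$exposure,
      exp_mediator = exp_tabs$mediator,
      exp_outcome = exp_tabs$outcome,
      med_mediator = med_tabs$mediator,
      med_exposure = med_tabs$exposure,
      med_outcome = med_tabs$outcome,
      truth = list(
        alpha = config$alpha, beta_med = config$beta_med,
        gamma_total = config$gamma_total, direct = direct,
        proportion = config$alpha * config$beta_med / config$gamma_total,
        seed = config$seed
      )
    ),
    class = "network_gwas_dataset"
  )
}
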