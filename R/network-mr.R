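# Network (mediation) Mendelian randomization: three pairwise MR fits
# combined into the alpha / beta / gamma decomposition.

#' Mediation decomposition from three causal-path estimates
#'
#' Product-of-coefficients mediation: with `alpha` the exposure -> mediator
#' path ("action theory"), `beta_med` the mediator -> outcome path
#' ("conceptual theory") and `gamma_total` the total exposure -> outcome
#' effect, the mediated (indirect) effect is `alpha * beta_med`, the
#' direct effect is `gamma_total - alpha * beta_med`, and the mediated
#' proportion is `alpha * beta_med / gamma_total` (reported both as a
#' fraction and as a truncated integer percent, matching the conventional
#' print style, e.g. 0.2954 -> 29). The indirect-effect SE is the
#' first-order delta method,
#' `sqrt(beta_med^2 se_alpha^2 + alpha^2 se_beta^2)`.
#'
#' @param alpha,beta_med,gamma_total Path estimates.
#' @param alpha_se,beta_med_se,gamma_total_se Their standard errors
#'   (default 0 for pure arithmetic).
#' @return A one-row tibble of class `mediation_result`: `alpha`,
#'   `beta_med`, `gamma_total`, `indirect`, `direct`, `proportion`,
#'   `proportion_pct`, `se_indirect`. `proportion` is `NA` (flagged by a
#'   warning) when `gamma_total = 0`.
#' @examples
#' mediation(0.13, 0.50, 0.22) # indirect 0.065, proportion 29%
#' @export
mediation <- function(alpha, beta_med, gamma_total,
                      alpha_se = 0, beta_med_se = 0, gamma_total_se = 0) {
  if (any(c(alpha_se, beta_med_se, gamma_total_se) < 0)) {
    pp_stop("standard errors must be >= 0")
  }
  indirect <- alpha * beta_med
  if (gamma_total == 0) {
    warning("`gamma_total` is 0: mediated proportion undefined", call. = FALSE)
    proportion <- NA_real_
    pct <- NA_real_
  } else {
    proportion <- indirect / gamma_total
    pct <- trunc(100 * proportion + sign(proportion) * 1e-9)
  }
  out <- tibble::tibble(
    alpha = alpha, beta_med = beta_med, gamma_total = gamma_total,
    indirect = indirect, direct = gamma_total - indirect,
    proportion = proportion, proportion_pct = pct,
    se_indirect = sqrt(beta_med^2 * alpha_se^2 + alpha^2 * beta_med_se^2)
  )
  class(out) <- c("mediation_result", class(out))
  out
}

edge_report <- function(exposure_stats, outcome_stats, model) {
  h <- harmonize(exposure_stats, outcome_stats)
  est <- ivw(h, model)
  q <- cochran_q(h, "ivw")
  eg <- if (nrow(h) >= 3) mr_egger(h) else NULL
  fs <- instrument_strength(h)
  tibble::tibble(
    beta = est$beta, se = est$se, p = est$p, n_snp = est$n_snp,
    q_statistic = q$statistic, q_p = q$p_value,
    egger_intercept = if (!is.null(eg)) {
      eg$beta[eg$method == "egger_intercept"]
    } else NA_real_,
    egger_intercept_p = if (!is.null(eg)) {
      eg$p[eg$method == "egger_intercept"]
    } else NA_real_,
    mean_f = fs$mean_f, min_f = fs$min_f
  )
}

#' Network MR: mediation analysis over GWAS summary-statistic triplets
#'
#' Estimates the three mediation paths by IVW two-sample MR -- `alpha`
#' from the exposure's instruments against the mediator, `beta` from the
#' mediator's instruments against the outcome, and the total effect
#' `gamma` from the exposure's instruments against the outcome -- plus the
#' reverse mediator -> exposure edge as a bidirectionality check. Each
#' edge carries its heterogeneity Q, Egger intercept and instrument-F
#' diagnostics; the mediated effect and proportion come from
#' [mediation()].
#'
#' @param exp_exposure,exp_mediator,exp_outcome Summary statistics of the
#'   exposure's instruments against the exposure, mediator and outcome.
#' @param med_mediator,med_exposure,med_outcome Summary statistics of the
#'   mediator's instruments against the mediator, exposure and outcome.
#' @param model IVW model (`"random"` default).
#' @return An object of class `network_mr`: `edges` tibble (one row per
#'   path with diagnostics), `mediation` ([mediation()] result), `model`.
#' @examples
#' gw <- simulate_network_gwas(network_gwas_config(seed = 2))
#' fit <- run_network_mr(
#'   gw$exp_exposure, gw$exp_mediator, gw$exp_outcome,
#'   gw$med_mediator, gw$med_exposure, gw$med_outcome
#' )
#' glance(fit)
#' @export
run_network_mr <- function(exp_exposure, exp_mediator, exp_outcome,
                           med_mediator, med_exposure, med_outcome,
                           model = c("random", "fixed")) {
  model <- match.arg(model)
  alpha <- edge_report(exp_exposure, exp_mediator, model)
  gamma <- edge_report(exp_exposure, exp_outcome, model)
  beta <- edge_report(med_mediator, med_outcome, model)
  reverse <- edge_report(med_mediator, med_exposure, model)
  edges <- dplyr::bind_rows(
    dplyr::mutate(alpha, path = "alpha (exposure -> mediator)", .before = 1),
    dplyr::mutate(beta, path = "beta (mediator -> outcome)", .before = 1),
    dplyr::mutate(gamma, path = "gamma (total, exposure -> outcome)", .before = 1),
    dplyr::mutate(reverse, path = "reverse (mediator -> exposure)", .before = 1)
  )
  med <- mediation(
    alpha$beta, beta$beta, gamma$beta,
    alpha$se, beta$se, gamma$se
  )
  structure(
    list(edges = edges, mediation = med, model = model),
    class = "network_mr"
  )
}

#' @export
print.network_mr <- function(x, ...) {
  cat("<network_mr> IVW path estimates (", x$model, " model)\n", sep = "")
  print(x$edges[c("path", "beta", "se", "p", "n_snp")])
  m <- x$mediation
  cat(sprintf(
    "mediated effect %.3f x %.3f = %.4f; proportion %.3f (%d%%)\n",
    m$alpha, m$beta_med, m$indirect, m$proportion, m$proportion_pct
  ))
  invisible(x)
}

#' @export
tidy.network_mr <- function(x, ...) x$edges

#' @export
glance.network_mr <- function(x, ...) x$mediation
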