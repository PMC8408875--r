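# Two-sample MR estimators and diagnostics.

sumstat_row <- function(snp, ea, oa, eaf, beta, se = 0.01, n = 1e5) {
  tibble::tibble(
    snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)), n = n
  )
}

test_that("harmonization aligns, flips and drops instruments correctly", {
  exp <- dplyr::bind_rows(
    sumstat_row("rs1", "A", "G", 0.3, 0.10),
    sumstat_row("rs2", "C", "T", 0.6, 0.20),
    sumstat_row("rs3", "A", "T", 0.50, 0.15), # ambiguous palindromic
    sumstat_row("rs4", "A", "G", 0.3, 0.12),
    sumstat_row("rs5", "A", "T", 0.10, 0.15) # palindromic but resolvable
  )
  out <- dplyr::bind_rows(
    sumstat_row("rs1", "G", "A", 0.7, -0.05), # swapped alleles
    sumstat_row("rs2", "C", "T", 0.6, 0.08), # identical
    sumstat_row("rs3", "A", "T", 0.50, 0.02),
    sumstat_row("rs4", "C", "G", 0.3, 0.04), # incompatible pair
    sumstat_row("rs5", "A", "T", 0.10, 0.03)
  )
  expect_warning(h <- harmonize(exp, out), "incompatible")
  expect_setequal(h$snp, c("rs1", "rs2", "rs5"))
  expect_equal(h$beta_out[h$snp == "rs1"], 0.05) # sign flipped
  expect_equal(h$beta_out[h$snp == "rs2"], 0.08) # unchanged
  expect_true(h$palindromic[h$snp == "rs5"])
  log <- attr(h, "log")
  expect_identical(log$action[log$snp == "rs3"], "drop_palindromic")
  expect_identical(log$action[log$snp == "rs4"], "drop_incompatible")
  expect_error(harmonize(exp[1, ], out[2, ]), "no shared SNPs")
})

test_that("Wald ratios follow the first-order formula", {
  h <- make_h(0.1, 0.05, se_exp = 0.005, se_out = 0.01)
  wr <- wald_ratio(h)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(make_h(0.1, 0))$beta, 0)
  expect_error(wald_ratio(make_h(0, 0.05)), "weak instrument")
})

test_that("the second-order Wald SE matches a parametric-bootstrap oracle", {
  gx <- 0.1
  sx <- 0.01 # gamma / se = 10
  gy <- 0.05
  sy <- 0.01
  h <- make_h(gx, gy, se_exp = sx, se_out = sy)
  se2 <- wald_ratio(h, se_order = "second")$se
  set.seed(40)
  draws <- (gy + rnorm(1e6, 0, sy)) / (gx + rnorm(1e6, 0, sx))
  expect_lt(abs(se2 - sd(draws)) / sd(draws), 0.05)
})

test_that("IVW reduces to the Wald ratio and averages symmetric instruments", {
  h1 <- make_h(0.1, 0.05, se_exp = 0.005, se_out = 0.01)
  e1 <- ivw(h1)
  w1 <- wald_ratio(h1)
  expect_equal(e1$beta, w1$beta)
  expect_equal(e1$se, w1$se)
  h2 <- make_h(c(1, 1), c(0.4, 0.6), se_out = c(0.05, 0.05))
  expect_equal(ivw(h2, "fixed")$beta, 0.5)
})

test_that("IVW equals a brute-force grid minimizer", {
  set.seed(41)
  for (i in 1:20) {
    J <- sample(3:30, 1)
    h <- make_h(
      rnorm(J, 0.1, 0.05), rnorm(J, 0.05, 0.05),
      se_exp = runif(J, 0.005, 0.02), se_out = runif(J, 0.005, 0.05)
    )
    grid <- oracle_ivw_grid(h)
    expect_lt(abs(ivw(h, "fixed")$beta - grid$beta),
              max(grid$resolution, 1e-7))
  }
})

test_that("estimators are invariant to instrument reorientation and order", {
  set.seed(42)
  gw <- simulate_gwas(gwas_config(n_snps = 20, seed = 43))
  h <- harmonize(gw$exposure, gw$outcome)
  flip <- sample(c(-1, 1), nrow(h), replace = TRUE)
  h2 <- dplyr::mutate(h, beta_exp = beta_exp * flip, beta_out = beta_out * flip)
  h3 <- h[sample(nrow(h)), ]
  for (href in list(h2, h3)) {
    expect_equal(ivw(href)$beta, ivw(h)$beta, tolerance = 1e-12)
    expect_equal(ivw(href)$se, ivw(h)$se, tolerance = 1e-12)
    expect_equal(mr_egger(href)$beta, mr_egger(h)$beta, tolerance = 1e-12)
    expect_equal(mr_raps(href)$beta, mr_raps(h)$beta, tolerance = 1e-8)
    expect_equal(cochran_q(href)$statistic, cochran_q(h)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("Egger with the intercept forced to zero equals fixed-effect IVW", {
  set.seed(44)
  h <- make_h(runif(10, 0.05, 0.2), rnorm(10, 0.05, 0.02),
              se_out = runif(10, 0.005, 0.02))
  e0 <- mr_egger(h, intercept = FALSE)
  iv <- ivw(h, "fixed")
  expect_equal(e0$beta, iv$beta, tolerance = 1e-12)
  expect_equal(e0$se, iv$se, tolerance = 1e-12)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("Cochran's Q is zero for identical ratios and calibrated under the null", {
  h <- make_h(c(1, 2, 4), c(0.5, 1, 2), se_out = c(0.1, 0.2, 0.4))
  q <- cochran_q(h)
  expect_equal(q$statistic, 0, tolerance = 1e-12)
  expect_equal(q$p_value, 1)

  set.seed(45)
  stats <- t(vapply(1:1000, function(i) {
    J <- 30
    gamma <- runif(J, 0.05, 0.2)
    se_out <- runif(J, 0.01, 0.03)
    h <- make_h(gamma, 0.5 * gamma + rnorm(J, 0, se_out),
                se_exp = 1e-8, se_out = se_out)
    q <- cochran_q(h)
    c(q$statistic / q$df, q$p_value)
  }, numeric(2)))
  expect_equal(mean(stats[, 1]), 1, tolerance = 0.1)
  expect_gt(suppressWarnings(stats::ks.test(stats[, 2], "punif"))$p.value, 0.01)
})

test_that("Cochran's Q detects a single displaced instrument", {
  hits <- vapply(1:100, function(i) {
    set.seed(4600 + i)
    J <- 30
    gamma <- runif(J, 0.05, 0.2)
    se_out <- rep(0.02, J)
    Gam <- 0.5 * gamma + rnorm(J, 0, se_out)
    Gam[1] <- Gam[1] + 10 * se_out[1]
    h <- make_h(gamma, Gam, se_exp = 1e-8, se_out = se_out)
    cochran_q(h)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("MR-PRESSO is deterministic, quiet on clean data, and flags outliers", {
  gw <- simulate_gwas(gwas_config(seed = 47))
  h <- harmonize(gw$exposure, gw$outcome)
  p1 <- mr_presso(h, n_sim = 500, seed = 9)
  p2 <- mr_presso(h, n_sim = 500, seed = 9)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$per_snp, p2$per_snp)
  expect_gt(p1$global_p, 0.05)
  expect_length(p1$outliers, 0)

  gwo <- simulate_gwas(gwas_config(n_outliers = 1, outlier_effect = 10, seed = 48))
  ho <- harmonize(gwo$exposure, gwo$outcome)
  po <- mr_presso(ho, n_sim = 1000, seed = 10)
  expect_lt(po$global_p, 0.05)
  expect_true(gwo$truth$outlier_snps %in% po$outliers)
  expect_false(is.na(po$distortion_p))
  expect_error(mr_presso(h[1:3, ]), "at least 4")
  expect_error(mr_presso(h, n_sim = 10), "at least 100")
})

test_that("MR-RAPS reduces to IVW when exposure noise vanishes", {
  set.seed(49)
  h <- make_h(runif(15, 0.05, 0.2), rnorm(15, 0.06, 0.03),
              se_exp = 1e-12, se_out = runif(15, 0.01, 0.03))
  expect_equal(mr_raps(h)$beta, ivw(h, "fixed")$beta, tolerance = 1e-8)
})

test_that("MR-RAPS agrees with IVW in the clean strong-instrument regime", {
  ok <- vapply(1:20, function(i) {
    gw <- simulate_gwas(gwas_config(seed = 5000 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    abs(mr_raps(h)$beta - ivw(h)$beta) <= ivw(h)$se
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("MR-RAPS recovers a planted overdispersion variance", {
  tau2 <- vapply(1:60, function(i) {
    gw <- simulate_gwas(gwas_config(pleiotropy_sd = 0.1, seed = 5100 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    attr(mr_raps(h, overdispersion = TRUE), "tau2")
  }, numeric(1))
  expect_gte(median(tau2), 0.005)
  expect_lte(median(tau2), 0.02)
})

test_that("the Huber loss variant is finite and robust to one outlier", {
  gw <- simulate_gwas(gwas_config(n_outliers = 1, outlier_effect = 15, seed = 52))
  h <- harmonize(gw$exposure, gw$outcome)
  plain <- mr_raps(h, overdispersion = TRUE)
  hub <- mr_raps(h, overdispersion = TRUE, loss = "huber")
  expect_true(is.finite(hub$beta) && hub$se > 0)
  expect_lte(abs(hub$beta - 0.5), abs(plain$beta - 0.5) + 0.02)
})

test_that("leave-one-out flags a dominant outlier and nothing else", {
  gw <- simulate_gwas(gwas_config(n_snps = 3, seed = 53))
  h <- harmonize(gw$exposure, gw$outcome)
  expect_equal(nrow(leave_one_out(h)), 3)

  gwc <- simulate_gwas(gwas_config(seed = 54))
  hc <- harmonize(gwc$exposure, gwc$outcome)
  expect_false(any(leave_one_out(hc)$influential))

  gwo <- simulate_gwas(gwas_config(n_outliers = 1, outlier_effect = 30, seed = 55))
  ho <- harmonize(gwo$exposure, gwo$outcome)
  loo <- leave_one_out(ho)
  expect_true(loo$influential[loo$snp == gwo$truth$outlier_snps])
})

test_that("instrument F statistics follow the squared-ratio definition", {
  x <- sumstat_row("rs1", "A", "G", 0.3, 0.1, se = 0.01)
  fs <- instrument_strength(x)
  expect_equal(fs$per_snp$f, 100)
  expect_equal(fs$n_strong, 1)
  zero <- instrument_strength(sumstat_row("rs2", "A", "G", 0.3, 0, se = 0.01))
  expect_equal(zero$per_snp$f, 0)
})

test_that("all estimators agree on clean simulated data", {
  for (i in 1:5) {
    gw <- simulate_gwas(gwas_config(seed = 5600 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    panel <- mr_all(h)
    betas <- panel$beta[panel$method %in% c("ivw", "egger", "raps")]
    ses <- panel$se[panel$method %in% c("ivw", "egger", "raps")]
    spread <- max(betas) - min(betas)
    expect_lt(spread, 2 * max(ses))
  }
})
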