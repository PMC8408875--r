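# Descriptive postprandial-inflammation analytics.

test_that("ln_plus_one transforms marker values", {
  expect_equal(ln_plus_one(0), 0)
  expect_equal(ln_plus_one(exp(1) - 1), 1)
  expect_equal(ln_plus_one(0.48), log(1.48))
  expect_error(ln_plus_one(-0.1), "non-negative")
})

test_that("percent change reproduces the printed cohort arithmetic", {
  expect_equal(percent_change(0.48, 1.29), 168.75)
  expect_equal(format_percent(percent_change(0.48, 1.29), "integer"), 169)
  expect_equal(percent_change(1.32, 1.38), 100 * 0.06 / 1.32)
  expect_equal(format_percent(percent_change(1.32, 1.38), "one_decimal"), 4.5)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_error(percent_change(0, 1), "strictly positive")
  # scale invariance
  expect_equal(percent_change(2.2, 3.3), percent_change(22, 33))
})

test_that("print conventions: integers round, one-decimal values truncate", {
  expect_equal(format_percent(168.75, "integer"), 169)
  expect_equal(format_percent(189.13, "integer"), 189)
  expect_equal(format_percent(42.769, "one_decimal"), 42.7)
  expect_equal(format_percent(100.952, "one_decimal"), 100.9)
  expect_equal(format_percent(13.63636363, "one_decimal"), 13.6)
})

make_markers <- function(h0, h6, marker = "GlycA") {
  n <- length(h0)
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:n), 2),
    marker = marker,
    time_h = rep(c(0, 6), each = n),
    value = c(h0, h6)
  )
}

test_that("responder summaries classify and summarize risers", {
  m <- make_markers(c(1.0, 1.0, 1.0), c(1.2, 0.8, 1.0))
  r <- responder_summary(m, "GlycA")
  expect_equal(r$fraction_rising, 1 / 3)
  expect_equal(r$responder_mean_rise, 0.2)
  expect_equal(r$responder_pct_rise, 20)
  expect_equal(r$fraction_rising + r$fraction_declining + r$fraction_unchanged, 1)

  # responder means 0.46 / 1.33 reproduce rise 0.87 and ~189%
  m2 <- make_markers(c(0.40, 0.52, 2, 2), c(1.20, 1.46, 1.5, 1.5), "IL-6")
  r2 <- responder_summary(m2, "IL-6")
  expect_equal(r2$responder_mean_fasting, 0.46)
  expect_equal(r2$responder_mean_6h, 1.33)
  expect_equal(r2$responder_mean_rise, 0.87)
  expect_equal(format_percent(r2$responder_pct_rise, "integer"), 189)

  all_down <- responder_summary(make_markers(c(1, 1), c(0.9, 0.8)), "GlycA")
  expect_equal(all_down$fraction_rising, 0)
  expect_true(is.na(all_down$responder_mean_rise))

  # tolerance band moves near-zero changes into "unchanged"
  m3 <- make_markers(c(1, 1, 1), c(1.001, 1.2, 0.999))
  r3 <- responder_summary(m3, "GlycA", epsilon = 0.01)
  expect_equal(r3$fraction_unchanged, 2 / 3)
  expect_error(responder_summary(m, "IL-6"), "no participants")
})

test_that("cross-sectional CV reproduces printed dispersion figures", {
  # two-point vectors with exactly the printed mean and SD
  mk <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  expect_equal(format_percent(cross_sectional_cv(mk(1.32, 0.18))$cv_pct, "one_decimal"), 13.6)
  expect_equal(format_percent(cross_sectional_cv(mk(0.48, 0.28))$cv_pct, "one_decimal"), 58.3)
  expect_equal(format_percent(cross_sectional_cv(mk(1.38, 0.28))$cv_pct, "one_decimal"), 20.2)
  expect_equal(format_percent(cross_sectional_cv(mk(1.29, 0.61))$cv_pct, "one_decimal"), 47.2)
  expect_equal(cross_sectional_cv(rep(2.5, 5))$cv_pct, 0)
  # scale invariance
  set.seed(1)
  x <- runif(50, 1, 2)
  expect_equal(cross_sectional_cv(x)$cv_pct, cross_sectional_cv(7 * x)$cv_pct)
  expect_error(cross_sectional_cv(c(1)), "at least 2")
  expect_error(cross_sectional_cv(c(-2, -1)), "mean")
})

test_that("Levene's test matches its definition and the reference implementation", {
  # identical multisets of absolute deviations -> W = 0, p = 1
  r0 <- levene_test(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  skip_if_not_installed("car")
  set.seed(8)
  x <- c(rnorm(40, 0, 1), rnorm(35, 2, 2.5), rnorm(30, -1, 0.6))
  g <- rep(c("a", "b", "c"), c(40, 35, 30))
  ours <- levene_test(x, g, center = "mean")
  ref <- car::leveneTest(x, factor(g), center = mean)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  ours_m <- levene_test(x, g, center = "median")
  ref_m <- car::leveneTest(x, factor(g), center = median)
  expect_equal(ours_m$statistic, ref_m[1, "F value"], tolerance = 1e-10)
  # invariance to per-group constant shifts
  shifted <- x + c(5, -3, 100)[match(g, c("a", "b", "c"))]
  expect_equal(levene_test(shifted, g)$statistic, ours$statistic, tolerance = 1e-10)
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "at least 2 obs")
})

test_that("Levene's test detects a ninefold variance ratio essentially always", {
  rej <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    levene_test(c(rnorm(200, 0, 1), rnorm(200, 0, 3)),
                rep(c("a", "b"), each = 200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("correlation matrix flags significance and respects affine invariance", {
  set.seed(10)
  n <- 60
  feats <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:n),
    f_linear = rnorm(n), f_noise = rnorm(n)
  )
  mk <- tibble::tibble(
    participant_id = rep(feats$participant_id, 1),
    marker = "GlycA", time_h = 6, value = 2 * feats$f_linear + 3
  )
  cm <- correlation_matrix(feats, mk)
  expect_equal(cm$r[cm$feature == "f_linear"], 1, tolerance = 1e-12)
  expect_true(cm$significant[cm$feature == "f_linear"])
  # affine transform of the feature leaves |r| unchanged
  feats2 <- dplyr::mutate(feats, f_linear = -4 * f_linear + 1)
  cm2 <- correlation_matrix(feats2, mk)
  expect_equal(abs(cm2$r[cm2$feature == "f_linear"]), 1, tolerance = 1e-12)

  set.seed(11)
  big <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:1000), f = rnorm(1000)
  )
  mkb <- tibble::tibble(
    participant_id = big$participant_id, marker = "GlycA",
    time_h = 0, value = rnorm(1000)
  )
  expect_lt(abs(correlation_matrix(big, mkb)$r), 0.1)
})

test_that("cohort correlations follow the planted structure", {
  sc <- small_cohort()
  cm <- correlation_matrix(sc$features, sc$data$markers)
  g6 <- dplyr::filter(cm, marker == "GlycA", time_h == 6)
  expect_gt(g6$r[g6$feature == "tg_at_6h"], g6$r[g6$feature == "glu_max1"])
})

# independent textbook computation of the mixed-design interaction F
oracle_mixed_anova_F <- function(y, group, subject, time) {
  G <- length(unique(group))
  Tn <- length(unique(time))
  N <- length(unique(subject))
  npg <- N / G
  grand <- mean(y)
  m_subj <- tapply(y, subject, mean)
  m_grp <- tapply(y, group, mean)
  m_time <- tapply(y, time, mean)
  m_gt <- tapply(y, list(group, time), mean)
  ss_between_subj <- Tn * sum((m_subj - grand)^2)
  ss_group <- npg * Tn * sum((m_grp - grand)^2)
  ss_time <- N * sum((m_time - grand)^2)
  ss_int <- npg * sum((m_gt - outer(m_grp, m_time, "+") + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_time - ss_int
  df_int <- (G - 1) * (Tn - 1)
  df_err <- (N - G) * (Tn - 1)
  (ss_int / df_int) / (ss_err_within / df_err)
}

test_that("repeated-measures interaction matches the textbook computation", {
  set.seed(12)
  n_per <- 4
  d <- expand.grid(
    subject = sprintf("S%02d", 1:(2 * n_per)), time_h = c(0, 4, 6)
  )
  d$sex <- ifelse(as.integer(factor(d$subject)) <= n_per, "F", "M")
  d$value <- rnorm(nrow(d), mean = 2 + (d$sex == "M") * d$time_h * 0.2)
  markers <- tibble::tibble(
    participant_id = as.character(d$subject), marker = "GlycA",
    time_h = d$time_h, value = d$value
  )
  covs <- dplyr::distinct(
    tibble::tibble(participant_id = as.character(d$subject), sex = d$sex)
  )
  ours <- rm_interaction_test(markers, covs, "GlycA", "sex")
  f_ref <- oracle_mixed_anova_F(d$value, d$sex, d$subject, d$time_h)
  expect_equal(ours$statistic, f_ref, tolerance = 1e-10)
  expect_equal(ours$df1, 2)
  expect_equal(ours$df2, (2 * n_per - 2) * 2)
})

test_that("identical trajectories in both groups give a null interaction", {
  # each male duplicates one female's trajectory exactly, so the per-sex
  # mean trajectories coincide while within-group variation remains
  set.seed(13)
  base <- matrix(rnorm(6, mean = 1.5, sd = 0.3), nrow = 2) # 2 subjects x 3 times
  markers <- tibble::tibble(
    participant_id = rep(sprintf("S%d", 1:4), each = 3),
    marker = "GlycA", time_h = rep(c(0, 4, 6), 4),
    value = c(t(rbind(base, base)))
  )
  covs <- tibble::tibble(
    participant_id = sprintf("S%d", 1:4), sex = c("F", "F", "M", "M")
  )
  r <- rm_interaction_test(markers, covs, "GlycA", "sex")
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_equal(r$p_value, 1, tolerance = 1e-10)
})

test_that("a planted sex-specific rise is detected with high power", {
  hits <- vapply(1:40, function(i) {
    dat <- simulate_cohort(cohort_config(
      n_participants = 200, seed = 600 + i,
      sex_rise_shift = c(glyca = 1, il6 = 0)
    ))
    rm_interaction_test(dat$markers, dat$covariates, "GlycA", "sex")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
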