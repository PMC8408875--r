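# Random-forest ranking, regression diagnostics and ROC analysis.

test_that("rf_rank puts a copied feature first and is seed-deterministic", {
  set.seed(20)
  n <- 120
  X <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 5), n)), paste0("f", 1:5)
  ))
  y <- X$f3
  r <- rf_rank(X, y, seed = 3)
  expect_identical(r$importance$feature[1], "f3")
  expect_equal(sum(r$importance$share), 1)
  # with every feature available at each split, the copy dominates
  r_full <- rf_rank(X, y, seed = 3, mtry = 5)
  expect_identical(r_full$importance$feature[1], "f3")
  expect_gt(r_full$importance$share[1], 0.5)
  r2 <- rf_rank(X, y, seed = 3)
  expect_identical(r$importance, r2$importance)
  expect_identical(r$q2, r2$q2)
  expect_error(rf_rank(X, rep(1, n)), "degenerate")
})

test_that("rf_rank Q2 stays near zero for a signal-free target", {
  set.seed(21)
  n <- 150
  X <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 6), n)), paste0("f", 1:6)
  ))
  y <- rnorm(n)
  q2 <- vapply(1:5, function(s) rf_rank(X, y, seed = s)$q2, numeric(1))
  expect_true(all(q2 <= 0.05))
})

test_that("Q2 never exceeds the in-sample R2 on synthetic cohorts", {
  sc <- small_cohort()
  md <- sc$model
  for (target in c("glyca_0h", "glyca_6h")) {
    r <- rf_rank(md[feature_names()], md[[target]], seed = 5)
    expect_lte(r$q2, r$r2)
  }
})

test_that("the planted TG feature ranks first for 6-h GlycA", {
  sc <- small_cohort()
  r <- rf_rank(sc$model[feature_names()], sc$model$glyca_6h, seed = 2)
  expect_identical(r$importance$feature[1], "tg_at_6h")
})

test_that("VIF matches its closed form and flags collinearity", {
  set.seed(22)
  n <- 10000
  a <- rnorm(n)
  b <- rnorm(n)
  v <- vif(tibble::tibble(a = a, b = b, c = rnorm(n)))
  expect_true(all(abs(v$vif - 1) < 0.01))
  expect_false(any(v$high))

  x <- rnorm(500)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(500)
  d2 <- tibble::tibble(x = x, y = y)
  r2 <- cor(x, y)^2
  expect_equal(vif(d2)$vif, rep(1 / (1 - r2), 2), tolerance = 1e-10)
  # r = 0.9 exactly gives 1/(1 - 0.81) = 5.263...
  expect_equal(1 / (1 - 0.9^2), 5.2632, tolerance = 1e-4)

  dup <- tibble::tibble(x = x, x2 = x, z = rnorm(500))
  vd <- vif(dup)
  expect_true(all(is.infinite(vd$vif[vd$feature %in% c("x", "x2")])))
  expect_true(all(vd$high[vd$feature %in% c("x", "x2")]))
})

test_that("multivariable_fit matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  exact <- suppressWarnings(
    multivariable_fit(tibble::tibble(y = 2 * x, x = x), "y", "x")
  )
  expect_equal(exact$terms$estimate[exact$terms$term == "x"], 2, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-12)

  set.seed(23)
  d <- tibble::tibble(x1 = rnorm(5), x2 = rnorm(5))
  d$y <- 1 + 0.5 * d$x1 - 2 * d$x2 + rnorm(5, 0, 0.3)
  fit <- multivariable_fit(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta_ref <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_equal(fit$terms$estimate, unname(beta_ref), tolerance = 1e-10)

  dd <- tibble::tibble(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(multivariable_fit(dd, "y", c("a", "b")), "collinear")
})

test_that("TG and first-glucose peaks independently predict 6-h GlycA", {
  sc <- small_cohort()
  fit <- multivariable_fit(sc$model, "glyca_6h", c("tg_max", "glu_max1"))
  pv <- fit$terms$p_value[fit$terms$term %in% c("tg_max", "glu_max1")]
  expect_true(all(pv < 0.05))
  expect_true(all(fit$terms$vif[!is.na(fit$terms$vif)] < 10))
})

test_that("percentile dichotomization uses the interpolated quantile", {
  d <- dichotomize_at_percentile(1:10, 70)
  expect_equal(d$cutoff, 7.3)
  expect_equal(which(d$labels == 1), 8:10)
  d0 <- dichotomize_at_percentile(c(3, 1, 2, 1), 0)
  expect_equal(d0$labels, as.integer(c(3, 1, 2, 1) > 1))
  expect_equal(dichotomize_at_percentile(rep(5, 4), 50)$labels, rep(0L, 4))
})

test_that("roc_auc equals exhaustive pair counting, with and without ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(24)
  for (i in 1:20) {
    n <- sample(8:50, 1)
    scores <- sample(1:8, n, replace = TRUE) # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly increasing score transforms", {
  set.seed(25)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(3 * scores + 10, labels)$auc, a)
})

test_that("null scores give AUC near one half", {
  set.seed(26)
  a <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(a$auc - 0.5), 0.04)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both outcome classes")
})

test_that("the DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(27)
  for (i in 1:5) {
    scores <- rnorm(120)
    labels <- rbinom(120, 1, 0.5)
    labels[1:2] <- c(0, 1)
    ours <- roc_auc(scores, labels)
    roc_ref <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                         quiet = TRUE)
    ref <- pROC::ci.auc(roc_ref, method = "delong")
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-6)
    expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-6)
  }
})
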