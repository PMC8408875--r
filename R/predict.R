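# Feature ranking and discrimination: cross-validated random forests,
# multivariable OLS with collinearity diagnostics, and percentile-cutoff
# ROC analysis.

#' Random-forest feature ranking with cross-validated Q-squared
#'
#' Fits a random-forest regression (via \pkg{ranger}) of `target` on the
#' numeric columns of `data`, ranks features by impurity-reduction
#' importance (normalized to sum 1), and estimates predictive ability by
#' k-fold cross-validation: `q2 = 1 - PRESS / TSS`, where PRESS is the sum
#' of held-out squared errors and TSS is the total sum of squares about the
#' grand mean. `r2` is the in-sample fit of the full-model predictions and
#' is labelled as such; a negative `q2` means the model predicts worse than
#' the mean.
#'
#' @param data Tibble of predictor columns (numeric); rows with missing
#'   values are dropped with a message.
#' @param target Numeric response vector, `nrow(data)` long.
#' @param n_folds Number of CV folds (default 5; requires
#'   `n >= 10 * n_folds`).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features tried per split; default `max(1, floor(p / 3))`.
#' @param seed Integer seed; results are deterministic given the seed
#'   (forests are grown single-threaded).
#' @return An object of class `rf_report`: list with `importance` tibble
#'   (`feature`, `importance`, `share`, `rank`), `r2`, `q2`, `n`,
#'   `n_trees`, `n_folds`, `mtry`, `seed`, `target`.
#' @export
rf_rank <- function(data, target, n_folds = 5, n_trees = 500,
                    mtry = NULL, seed = 1L) {
  data <- tibble::as_tibble(data)
  data <- data[vapply(data, is.numeric, logical(1))]
  if (length(data) == 0) pp_stop("`data` has no numeric predictor columns")
  check_numeric(target, "target")
  if (length(target) != nrow(data)) {
    pp_stop("`target` must have one value per row of `data`")
  }
  ok <- complete.cases(data) & !is.na(target)
  if (any(!ok)) {
    message(sprintf("%d row(s) with missing values dropped", sum(!ok)))
  }
  data <- data[ok, ]
  y <- target[ok]
  n <- nrow(data)
  if (var(y) == 0) pp_stop("degenerate target: constant response")
  if (n < 10 * n_folds) {
    pp_stop(sprintf("need n >= %d rows for %d-fold CV", 10 * n_folds, n_folds))
  }
  p <- ncol(data)
  mtry <- mtry %||% max(1, floor(p / 3))
  target_name <- deparse(substitute(target))

  df <- data
  df$.y <- y
  fit_rf <- function(train, sd) {
    ranger::ranger(
      dependent.variable.name = ".y", data = train,
      num.trees = n_trees, mtry = mtry, importance = "impurity",
      seed = sd, num.threads = 1
    )
  }
  full <- fit_rf(df, seed)
  pred_in <- predict(full, data = df, num.threads = 1)$predictions
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pred_in)^2) / tss

  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  press <- 0
  for (k in seq_len(n_folds)) {
    hold <- fold == k
    fit_k <- fit_rf(df[!hold, ], seed + k)
    pred_k <- predict(fit_k, data = df[hold, ], num.threads = 1)$predictions
    press <- press + sum((y[hold] - pred_k)^2)
  }
  q2 <- 1 - press / tss

  imp <- full$variable.importance
  imp[imp < 0] <- 0
  importance <- tibble::tibble(
    feature = names(imp), importance = unname(imp),
    share = unname(imp) / sum(imp)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(
    list(
      importance = importance, r2 = r2, r2_type = "in-sample", q2 = q2,
      n = n, n_trees = n_trees, n_folds = n_folds, mtry = mtry,
      seed = seed, target = target_name
    ),
    class = "rf_report"
  )
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf(
    "<rf_report> target %s: R2 (%s) = %.3f, Q2 (CV) = %.3f [n = %d, %d trees, %d folds]\n",
    x$target, x$r2_type, x$r2, x$q2, x$n, x$n_trees, x$n_folds
  ))
  print(head(x$importance, 5))
  invisible(x)
}

#' @export
tidy.rf_report <- function(x, ...) x$importance

#' @export
glance.rf_report <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, q2 = x$q2, n = x$n, n_trees = x$n_trees,
    n_folds = x$n_folds, mtry = x$mtry
  )
}

#' Plot random-forest importance shares
#'
#' @param object An `rf_report` from [rf_rank()].
#' @param ... Unused.
#' @return A ggplot bar chart of normalized importance by feature.
#' @export
autoplot.rf_report <- function(object, ...) {
  imp <- object$importance
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$share), y = .data$share
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Importance share",
      title = sprintf("Random-forest feature ranking (%s)", object$target)
    )
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` from regressing each feature on all others;
#' values above 10 are flagged as high collinearity. Exactly collinear
#' features are reported with infinite VIF.
#'
#' @param data Tibble of numeric feature columns (n > p + 1 complete rows).
#' @return A tibble with `feature`, `vif`, `high` (`vif > 10`).
#' @export
vif <- function(data) {
  data <- tibble::as_tibble(data)
  data <- data[vapply(data, is.numeric, logical(1))]
  data <- data[complete.cases(data), ]
  p <- ncol(data)
  if (p < 2) pp_stop("VIF needs at least 2 features")
  if (nrow(data) <= p + 1) pp_stop("need n > p + 1 rows")
  out <- purrr::map_dbl(names(data), function(v) {
    # a perfect fit here is the collinearity being diagnosed, not an error
    r2 <- suppressWarnings(summary(lm(
      as.formula(paste0("`", v, "` ~ .")),
      data = data
    ))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  tibble::tibble(feature = names(data), vif = out, high = out > 10)
}

#' Multivariable linear regression with standardized coefficients
#'
#' Ordinary least squares of `outcome` on `predictors`, reporting raw and
#' standardized coefficients (from z-scored variables), per-coefficient
#' two-sided t-tests, model R-squared, and VIFs when there are two or more
#' predictors.
#'
#' @param data Tibble containing the outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names; default
#'   all other numeric columns.
#' @return An object of class `lm_report` with a `terms` tibble
#'   (`term`, `estimate`, `std_beta`, `se`, `p_value`, `vif`), `r2`, `n`
#'   and the underlying `fit`.
#' @export
multivariable_fit <- function(data, outcome, predictors = NULL) {
  data <- tibble::as_tibble(data)
  check_columns(data, outcome, "data")
  predictors <- predictors %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))], outcome
  )
  check_columns(data, predictors, "data")
  d <- data[c(outcome, predictors)]
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n <= length(predictors) + 1) pp_stop("need n > p + 1 complete rows")

  f <- as.formula(paste0(
    "`", outcome, "` ~ ", paste0("`", predictors, "`", collapse = " + ")
  ))
  fit <- lm(f, data = d)
  if (fit$rank < length(predictors) + 1) {
    alias <- names(coef(fit))[is.na(coef(fit))]
    pp_stop(sprintf(
      "singular design: collinear predictor(s) %s", paste(alias, collapse = ", ")
    ))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  sds <- vapply(d, sd, numeric(1))
  terms <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    se = unname(ct[, "Std. Error"]),
    p_value = unname(ct[, "Pr(>|t|)"])
  )
  terms$std_beta <- NA_real_
  for (pr in predictors) {
    row <- match(paste0("`", pr, "`"), terms$term, nomatch = match(pr, terms$term))
    terms$term[row] <- pr
    terms$std_beta[row] <- terms$estimate[row] * sds[pr] / sds[outcome]
  }
  terms$vif <- NA_real_
  if (length(predictors) >= 2) {
    v <- vif(d[predictors])
    terms$vif[match(v$feature, terms$term)] <- v$vif
  }
  structure(
    list(
      terms = terms[c("term", "estimate", "std_beta", "se", "p_value", "vif")],
      outcome = outcome, r2 = sm$r.squared, n = n, fit = fit
    ),
    class = "lm_report"
  )
}

#' @export
print.lm_report <- function(x, ...) {
  cat(sprintf("<lm_report> %s: R2 = %.3f, n = %d\n", x$outcome, x$r2, x$n))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.lm_report <- function(x, ...) x$terms

#' @export
glance.lm_report <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, r2 = x$r2, n = x$n)
}

#' Dichotomize values at an empirical percentile
#'
#' Labels a value 1 when it exceeds the `pct`-th empirical percentile
#' (linear-interpolation quantile), e.g. `pct = 70` defines the top-30%
#' "high inflammatory response" class.
#'
#' @param values Numeric vector (n >= 2).
#' @param pct Percentile in 0--100.
#' @return A list with `labels` (integer 0/1) and `cutoff`.
#' @examples
#' dichotomize_at_percentile(1:10, 70) # cutoff 7.3; 8, 9, 10 labelled 1
#' @export
dichotomize_at_percentile <- function(values, pct) {
  check_numeric(values, "values")
  if (length(values) < 2) pp_stop("need at least 2 values")
  if (pct < 0 || pct > 100) pp_stop("`pct` must be in [0, 100]")
  cutoff <- quantile(values, pct / 100, type = 7, names = FALSE, na.rm = TRUE)
  list(labels = as.integer(values > cutoff), cutoff = cutoff)
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC via the Mann--Whitney U identity with tie correction (ties count
#' one half), with a 95\% CI from the DeLong placement-value variance
#' estimator. ROC points over all score thresholds are attached.
#'
#' @param scores Numeric discrimination scores.
#' @param labels Binary outcome labels (0/1 or logical); both classes must
#'   be present.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `roc_report`: `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_pos`, `n_neg`, and a `points` tibble (`threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  check_numeric(scores, "scores")
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) pp_stop("`labels` must be binary 0/1")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0 || n0 == 0) pp_stop("both outcome classes must be present")

  # placement values (DeLong): V10_i = P(neg < pos_i) + 0.5 P(neg == pos_i)
  v10 <- vapply(pos, function(x) (sum(neg < x) + 0.5 * sum(neg == x)) / n0, 0)
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / n1, 0)
  auc <- mean(v10)
  s10 <- if (n1 > 1) var(v10) else 0
  s01 <- if (n0 > 1) var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(pos >= t), 0),
    fpr = vapply(thr, function(t) mean(neg >= t), 0)
  )
  structure(
    list(
      auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
      conf_level = conf_level, n_pos = n1, n_neg = n0, points = points
    ),
    class = "roc_report"
  )
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf(
    "<roc_report> AUC = %.3f (%g%% CI %.3f-%.3f), %d pos / %d neg\n",
    x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
tidy.roc_report <- function(x, ...) x$points

#' @export
glance.roc_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#'
#' @param object A `roc_report` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_report <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf(
        "ROC: AUC = %.3f (%.3f-%.3f)", object$auc, object$ci_low, object$ci_high
      )
    )
}
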