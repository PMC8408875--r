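# Manifest-variable path analysis: maximum-likelihood fitting of a
# recursive linear system on observed variables, standardized coefficients
# and the chi-square / CFI / TLI / RMSEA fit panel.

#' Specify a manifest-variable path model
#'
#' A directed acyclic graph on observed variables. Exogenous variables
#' (those receiving no edge) get freely estimated variances and pairwise
#' covariances; each endogenous variable gets a free residual variance.
#'
#' @param edges Either a character vector of `"source -> target"` strings
#'   or a two-column data frame (`from`, `to`).
#' @return An object of class `path_spec` with `nodes`, `edges` (tibble
#'   `from`, `to`), and `exogenous`.
#' @examples
#' path_spec(c("vfm -> tg_fasting", "tg_fasting -> glyca_0h", "vfm -> glyca_0h"))
#' @export
path_spec <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(trimws(edges), "\\s*->\\s*")
    bad <- lengths(parts) != 2
    if (any(bad)) {
      pp_stop(sprintf(
        "malformed edge(s): %s (expected 'source -> target')",
        paste(edges[bad], collapse = "; ")
      ))
    }
    edges <- tibble::tibble(
      from = vapply(parts, `[`, "", 1),
      to = vapply(parts, `[`, "", 2)
    )
  } else {
    edges <- tibble::as_tibble(edges)
    check_columns(edges, c("from", "to"), "edges")
  }
  if (nrow(edges) == 0) pp_stop("at least one edge is required")
  if (any(edges$from == edges$to)) pp_stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges$from, edges$to))) pp_stop("duplicate edges")
  nodes <- union(edges$from, edges$to)

  # Kahn topological sort to verify acyclicity
  remaining <- edges
  order <- character(0)
  avail <- setdiff(nodes, remaining$to)
  while (length(avail) > 0) {
    v <- avail[1]
    order <- c(order, v)
    avail <- avail[-1]
    remaining <- remaining[remaining$from != v, ]
    newly <- setdiff(setdiff(nodes, order), remaining$to)
    avail <- union(avail, setdiff(newly, avail))
  }
  if (length(order) < length(nodes)) {
    pp_stop("the path specification contains a cycle")
  }
  structure(
    list(nodes = nodes, edges = edges, exogenous = setdiff(nodes, edges$to)),
    class = "path_spec"
  )
}

# Model-implied covariance for x = B x + e: Sigma = (I-B)^-1 Psi (I-B)^-T
implied_cov <- function(B, Psi) {
  IB <- solve(diag(nrow(B)) - B)
  IB %*% Psi %*% t(IB)
}

#' Fit indices for a covariance-structure model
#'
#' Comparative fit index, Tucker--Lewis index and RMSEA from the model and
#' baseline (independence) chi-square statistics:
#' \deqn{CFI = 1 - \max(\chi^2_m - df_m, 0) / \max(\chi^2_b - df_b, \chi^2_m - df_m, 0)}
#' \deqn{TLI = ((\chi^2_b/df_b) - (\chi^2_m/df_m)) / ((\chi^2_b/df_b) - 1)}
#' \deqn{RMSEA = \sqrt{\max(\chi^2_m - df_m, 0) / (df_m (n - 1))}}
#' TLI above 1 is capped at 1 by convention with the raw value retained;
#' TLI and RMSEA are `NA` when `df_m = 0`.
#'
#' @param chi2_m,df_m Model chi-square and degrees of freedom.
#' @param chi2_b,df_b Baseline (independence) chi-square and df
#'   (`df_b >= df_m`).
#' @param n Sample size (>= 2).
#' @return A one-row tibble: `cfi`, `tli`, `tli_raw`, `rmsea`.
#' @examples
#' fit_indices(20, 5, 1000, 10, 101)
#' @export
fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n) {
  if (df_m < 0 || df_b < df_m) pp_stop("need df_b >= df_m >= 0")
  if (n < 2) pp_stop("need n >= 2")
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (df_m == 0) {
    tli_raw <- NA_real_
    rmsea <- NA_real_
  } else {
    rb <- chi2_b / df_b
    tli_raw <- (rb - chi2_m / df_m) / (rb - 1)
    rmsea <- sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1)))
  }
  tibble::tibble(
    cfi = cfi, tli = if (is.na(tli_raw)) NA_real_ else min(tli_raw, 1),
    tli_raw = tli_raw, rmsea = rmsea
  )
}

#' Fit a manifest-variable path model by maximum likelihood
#'
#' Estimates edge coefficients, residual variances and exogenous
#' (co)variances by minimizing the ML discrepancy
#' \deqn{F = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \log|S| - p}
#' between the model-implied and sample covariance matrices, using
#' complete-case rows. For a recursive system the equation-wise
#' least-squares solution computed from S is the global optimum and is used
#' as the start; a quasi-Newton polish (log-variance / Cholesky
#' parametrization keeps Psi positive definite) then verifies convergence.
#' `chi2 = (n - 1) F` at the optimum; standard errors come from the inverse
#' observed information; standardized coefficients are
#' `estimate * sd(source) / sd(target)`.
#'
#' @param data Tibble with numeric columns for every node in `spec`.
#' @param spec A [path_spec()].
#' @param conv_tol Relative convergence tolerance on F (default 1e-8).
#' @return An object of class `path_fit`: `edges` tibble (`from`, `to`,
#'   `estimate`, `std_beta`, `se`, `p_value`), `variances` tibble, `chi2`,
#'   `df`, `baseline_chi2`, `baseline_df`, `cfi`, `tli`, `tli_raw`,
#'   `rmsea`, `n`, `n_free`, `discrepancy`, `converged`.
#' @export
fit_path_model <- function(data, spec, conv_tol = 1e-8) {
  if (!inherits(spec, "path_spec")) pp_stop("`spec` must be a path_spec()")
  data <- tibble::as_tibble(data)
  check_columns(data, spec$nodes, "data")
  X <- data[spec$nodes]
  nonnum <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    pp_stop(sprintf(
      "non-numeric node column(s): %s (encode factors numerically first)",
      paste(nonnum, collapse = ", ")
    ))
  }
  X <- as.matrix(X[complete.cases(X), ])
  n <- nrow(X)
  p <- ncol(X)
  S <- cov(X)
  vars <- spec$nodes
  exo <- spec$exogenous
  endo <- setdiff(vars, exo)
  n_exo <- length(exo)
  ne <- nrow(spec$edges)
  n_free <- ne + n_exo * (n_exo + 1) / 2 + length(endo)
  df_m <- p * (p + 1) / 2 - n_free
  if (df_m < 0) pp_stop("model has more free parameters than covariance moments")
  if (n < 5 * n_free) {
    pp_stop(sprintf("need at least %d complete rows (5 per free parameter)", 5 * n_free))
  }

  ei <- match(spec$edges$from, vars)
  ej <- match(spec$edges$to, vars)
  exo_i <- match(exo, vars)
  endo_i <- match(endo, vars)
  # Cholesky index layout for the exogenous block (lower triangle, by column)
  chol_idx <- which(lower.tri(matrix(0, n_exo, n_exo), diag = TRUE), arr.ind = TRUE)

  unpack <- function(theta) {
    B <- matrix(0, p, p)
    B[cbind(ej, ei)] <- theta[seq_len(ne)]
    L <- matrix(0, n_exo, n_exo)
    lt <- theta[ne + seq_len(nrow(chol_idx))]
    diag_pos <- chol_idx[, 1] == chol_idx[, 2]
    lt[diag_pos] <- exp(lt[diag_pos]) # log-diagonal keeps the block PD
    L[chol_idx] <- lt
    Psi <- matrix(0, p, p)
    Psi[exo_i, exo_i] <- L %*% t(L)
    resv <- exp(theta[ne + nrow(chol_idx) + seq_along(endo_i)])
    Psi[cbind(endo_i, endo_i)] <- resv
    list(B = B, Psi = Psi)
  }

  logdetS <- determinant(S, logarithm = TRUE)$modulus
  Fml <- function(theta) {
    par <- unpack(theta)
    Sig <- implied_cov(par$B, par$Psi)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    val <- ld + tr - logdetS - p
    if (!is.finite(val)) 1e10 else as.numeric(val)
  }

  # start: exact recursive-system solution computed from S
  start_b <- numeric(ne)
  start_res <- numeric(length(endo_i))
  for (k in seq_along(endo_i)) {
    yi <- endo_i[k]
    pa <- ei[ej == yi]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, yi])
    start_b[ej == yi] <- b[match(ei[ej == yi], pa)]
    start_res[k] <- max(S[yi, yi] - sum(b * S[pa, yi]), 1e-8)
  }
  Lex <- t(chol(S[exo_i, exo_i, drop = FALSE]))
  lt0 <- Lex[chol_idx]
  diag_pos <- chol_idx[, 1] == chol_idx[, 2]
  lt0[diag_pos] <- log(lt0[diag_pos])
  start <- c(start_b, lt0, log(start_res))

  opt <- optim(
    start, Fml, method = "BFGS",
    control = list(maxit = 500, reltol = conv_tol)
  )
  if (opt$convergence != 0 && opt$value > Fml(start) + 1e-10) {
    pp_stop(sprintf(
      "path-model optimization did not converge (code %d, F = %.6g)",
      opt$convergence, opt$value
    ))
  }
  theta <- opt$par
  Fmin <- opt$value

  # observed information on the likelihood scale: H of (n-1)/2 * F
  H <- tryCatch(
    optimHess(theta, function(th) (n - 1) / 2 * Fml(th)),
    error = function(e) NULL
  )
  se_theta <- rep(NA_real_, length(theta))
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      dg <- diag(Hi)
      se_theta[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  se_b <- se_theta[seq_len(ne)]

  sds <- sqrt(diag(S))
  est <- theta[seq_len(ne)]
  edges <- tibble::tibble(
    from = spec$edges$from, to = spec$edges$to,
    estimate = unname(est),
    std_beta = unname(est * sds[ei] / sds[ej]),
    se = se_b,
    p_value = 2 * pnorm(-abs(est / se_b))
  )
  par <- unpack(theta)
  variances <- tibble::tibble(
    node = c(exo, endo),
    type = c(rep("exogenous", n_exo), rep("residual", length(endo))),
    variance = c(diag(par$Psi)[exo_i], diag(par$Psi)[endo_i])
  )

  chi2 <- max((n - 1) * Fmin, 0)
  R <- cov2cor(S)
  chi2_b <- as.numeric(-(n - 1) * determinant(R, logarithm = TRUE)$modulus)
  df_b <- p * (p - 1) / 2
  fi <- fit_indices(chi2, df_m, chi2_b, df_b, n)

  structure(
    list(
      edges = edges, variances = variances,
      chi2 = chi2, df = df_m, baseline_chi2 = chi2_b, baseline_df = df_b,
      cfi = fi$cfi, tli = fi$tli, tli_raw = fi$tli_raw, rmsea = fi$rmsea,
      n = n, n_free = n_free, discrepancy = Fmin,
      converged = opt$convergence == 0,
      sample_cov = S, spec = spec
    ),
    class = "path_fit"
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf(
    "<path_fit> chi2 = %.2f (df %d), CFI = %.3f, TLI = %.3f, RMSEA = %.3f, n = %d\n",
    x$chi2, x$df, x$cfi, x$tli, x$rmsea, x$n
  ))
  print(x$edges)
  invisible(x)
}

#' @export
tidy.path_fit <- function(x, ...) x$edges

#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, df = x$df, cfi = x$cfi, tli = x$tli, tli_raw = x$tli_raw,
    rmsea = x$rmsea, baseline_chi2 = x$baseline_chi2,
    baseline_df = x$baseline_df, n = x$n, n_free = x$n_free,
    converged = x$converged
  )
}

#' Select covariates for a path model by random-forest importance
#'
#' Ranks candidate columns with [rf_rank()] and returns the top-k feature
#' names. With `exclude_postprandial = TRUE`, postprandial glycemia and
#' lipemia features (everything except the fasting values) are filtered
#' out before ranking, mirroring the practice of excluding them when they
#' render the structural model inadmissible.
#'
#' @param data Tibble of candidate covariate columns (numeric).
#' @param target Numeric response vector.
#' @param k Number of covariates to keep (default 6).
#' @param exclude_postprandial Drop postprandial curve features first.
#' @param seed,n_trees Passed to [rf_rank()].
#' @return Character vector of selected column names (possibly empty).
#' @export
select_sem_inputs <- function(data, target, k = 6,
                              exclude_postprandial = FALSE,
                              seed = 1L, n_trees = 500) {
  if (k == 0) return(character(0))
  data <- tibble::as_tibble(data)
  if (exclude_postprandial) {
    data <- data[setdiff(names(data), feature_names("postprandial"))]
  }
  rf <- rf_rank(data, target, n_trees = n_trees, seed = seed)
  head(rf$importance$feature, k)
}
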