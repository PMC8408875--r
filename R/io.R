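# Tab-separated readers and writers for the pipeline's tables, plus the
# end-to-end pipeline driver. TSV with '.' decimals is fixed by design to
# avoid locale issues; write -> read round-trips values at full precision.

read_table_checked <- function(path, cols, what) {
  if (!file.exists(path)) pp_stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) pp_stop(sprintf("empty input file: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) pp_stop(sprintf("no data rows in %s", path))
  check_columns(df, names(cols), what)
  for (nm in names(cols)) {
    if (cols[[nm]] == "numeric" && !is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))) & !is.na(df[[nm]]))
      pp_stop(sprintf(
        "non-numeric values in column `%s` of %s (e.g. row %s)",
        nm, path, if (length(bad) > 0) bad[1] else "?"
      ))
    }
  }
  tibble::as_tibble(df)
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write long-format postprandial curves
#'
#' Schema: `participant_id`, `analyte`, `time_min`, `value` (TSV).
#'
#' @param path File path.
#' @param curves Curve tibble to write.
#' @return `read_curves()` a tibble; `write_curves()` the path, invisibly.
#' @export
read_curves <- function(path) {
  read_table_checked(
    path,
    c(participant_id = "character", analyte = "character",
      time_min = "numeric", value = "numeric"),
    "curves file"
  )
}

#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  check_columns(curves, c("participant_id", "analyte", "time_min", "value"), "curves")
  write_tsv_plain(curves, path)
}

#' Read and write marker series
#'
#' Schema: `participant_id`, `marker`, `time_h`, `value` (TSV).
#'
#' @param path File path.
#' @param markers Marker tibble to write.
#' @return `read_markers()` a tibble; `write_markers()` the path, invisibly.
#' @export
read_markers <- function(path) {
  read_table_checked(
    path,
    c(participant_id = "character", marker = "character",
      time_h = "numeric", value = "numeric"),
    "markers file"
  )
}

#' @rdname read_markers
#' @export
write_markers <- function(markers, path) {
  check_columns(markers, c("participant_id", "marker", "time_h", "value"), "markers")
  write_tsv_plain(markers, path)
}

#' Read and write participant covariates
#'
#' Schema: `participant_id` plus covariate columns (TSV).
#'
#' @param path File path.
#' @param covariates Covariate tibble to write.
#' @return `read_covariates()` a tibble; `write_covariates()` the path,
#'   invisibly.
#' @export
read_covariates <- function(path) {
  read_table_checked(path, c(participant_id = "character"), "covariates file")
}

#' @rdname read_covariates
#' @export
write_covariates <- function(covariates, path) {
  check_columns(covariates, "participant_id", "covariates")
  write_tsv_plain(covariates, path)
}

#' Read and write GWAS summary statistics
#'
#' Schema: `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n` (TSV).
#'
#' @param path File path.
#' @param stats Summary-statistic tibble to write.
#' @return `read_summary_stats()` a tibble; `write_summary_stats()` the
#'   path, invisibly.
#' @export
read_summary_stats <- function(path) {
  read_table_checked(
    path,
    c(snp = "character", effect_allele = "character",
      other_allele = "character", eaf = "numeric", beta = "numeric",
      se = "numeric", pval = "numeric", n = "numeric"),
    "summary-statistics file"
  )
}

#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(stats, path) {
  check_columns(stats, sumstat_cols, "summary statistics")
  write_tsv_plain(stats, path)
}

#' Run the full analysis pipeline into a directory
#'
#' Simulates (or reuses) a cohort and a network-MR GWAS triplet, then runs
#' the toggled stages in order: curve featurization, inflammatory-response
#' characterization, random-forest / regression / ROC prediction, path
#' modelling, the MR method panel, and network-MR mediation. Every stage's
#' tables are written as TSV (plus a JSON truth sidecar and a manifest of
#' file hashes), so a rerun with the same configuration reproduces
#' identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_config()].
#' @param network A [network_gwas_config()].
#' @param stages Character vector of stages to run, a subset of the
#'   default.
#' @return Invisibly, a list with each stage's in-memory results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(out_dir,
                         cohort = cohort_config(),
                         network = network_gwas_config(),
                         stages = c("features", "characterize", "predict",
                                    "pathmodel", "mr", "network_mr")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  dat <- simulate_cohort(cohort)
  write_curves(dat$curves, file.path(out_dir, "curves.tsv"))
  write_markers(dat$markers, file.path(out_dir, "markers.tsv"))
  write_covariates(dat$covariates, file.path(out_dir, "covariates.tsv"))
  jsonlite::write_json(
    dat$truth, file.path(out_dir, "truth_cohort.json"),
    auto_unbox = TRUE, digits = NA
  )
  res$cohort <- dat

  gw <- simulate_network_gwas(network)
  for (nm in c("exp_exposure", "exp_mediator", "exp_outcome",
               "med_mediator", "med_exposure", "med_outcome")) {
    write_summary_stats(gw[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(
    gw$truth, file.path(out_dir, "truth_gwas.json"),
    auto_unbox = TRUE, digits = NA
  )
  res$gwas <- gw

  feats <- NULL
  if (any(c("features", "predict", "pathmodel") %in% stages)) {
    feats <- extract_curve_features(dat$curves)
  }
  if ("features" %in% stages) {
    write_tsv_plain(feats, file.path(out_dir, "features.tsv"))
    res$features <- feats
  }

  markers_wide <- dat$markers |>
    tidyr::pivot_wider(
      id_cols = "participant_id", names_from = c("marker", "time_h"),
      values_from = "value", names_glue = "{marker}_{time_h}h"
    ) |>
    dplyr::rename_with(~ tolower(gsub("-", "", .x)))

  if ("characterize" %in% stages) {
    resp <- dplyr::bind_rows(
      responder_summary(dat$markers, "GlycA"),
      responder_summary(dat$markers, "IL-6")
    )
    cvs <- dat$markers |>
      dplyr::group_by(.data$marker, .data$time_h) |>
      dplyr::group_modify(~ cross_sectional_cv(.x$value)) |>
      dplyr::ungroup()
    cors <- correlation_matrix(feats %||% extract_curve_features(dat$curves),
                               dat$markers)
    lev <- dat$markers |>
      dplyr::inner_join(dat$covariates[c("participant_id", "sex")],
                        by = "participant_id") |>
      dplyr::group_by(.data$marker, .data$time_h) |>
      dplyr::group_modify(~ levene_test(.x$value, .x$sex)) |>
      dplyr::ungroup()
    inter <- dplyr::bind_rows(
      rm_interaction_test(dat$markers, dat$covariates, "GlycA", "sex"),
      rm_interaction_test(dat$markers, dat$covariates, "GlycA", "age_group"),
      rm_interaction_test(dat$markers, dat$covariates, "IL-6", "sex"),
      rm_interaction_test(dat$markers, dat$covariates, "IL-6", "age_group")
    )
    write_tsv_plain(resp, file.path(out_dir, "responders.tsv"))
    write_tsv_plain(cvs, file.path(out_dir, "dispersion.tsv"))
    write_tsv_plain(cors, file.path(out_dir, "correlations.tsv"))
    write_tsv_plain(lev, file.path(out_dir, "levene.tsv"))
    write_tsv_plain(inter, file.path(out_dir, "interactions.tsv"))
    res$characterize <- list(
      responders = resp, dispersion = cvs, correlations = cors,
      levene = lev, interactions = inter
    )
  }

  if ("predict" %in% stages) {
    md <- dplyr::inner_join(feats, markers_wide, by = "participant_id")
    rf <- rf_rank(
      md[feature_names("all")], md$glyca_6h, seed = cohort$seed
    )
    mv <- multivariable_fit(
      md, "glyca_6h", c("tg_max", "glu_max1")
    )
    dic <- dichotomize_at_percentile(md$glyca_6h, 70)
    roc <- roc_auc(md$tg_max, dic$labels)
    write_tsv_plain(tidy(rf), file.path(out_dir, "rf_importance.tsv"))
    write_tsv_plain(tidy(mv), file.path(out_dir, "regression.tsv"))
    write_tsv_plain(glance(roc), file.path(out_dir, "roc.tsv"))
    res$predict <- list(rf = rf, regression = mv, roc = roc)
  }

  if ("pathmodel" %in% stages) {
    md <- feats |>
      dplyr::inner_join(markers_wide, by = "participant_id") |>
      dplyr::inner_join(dat$covariates, by = "participant_id")
    spec <- path_spec(c(
      "vfm -> tg_fasting",
      "vfm -> glyca_0h",
      "tg_fasting -> glyca_0h",
      "glu_fasting -> glyca_0h",
      "glyca_0h -> glyca_6h"
    ))
    pf <- fit_path_model(md, spec)
    write_tsv_plain(tidy(pf), file.path(out_dir, "path_edges.tsv"))
    write_tsv_plain(glance(pf), file.path(out_dir, "path_fit.tsv"))
    res$pathmodel <- pf
  }

  if ("mr" %in% stages) {
    h <- harmonize(gw$exp_exposure, gw$exp_outcome)
    panel <- mr_all(h)
    presso <- mr_presso(h, seed = network$seed)
    loo <- leave_one_out(h)
    fs <- instrument_strength(gw$exp_exposure)
    write_tsv_plain(panel, file.path(out_dir, "mr_estimates.tsv"))
    write_tsv_plain(
      attr(panel, "heterogeneity"), file.path(out_dir, "mr_heterogeneity.tsv")
    )
    write_tsv_plain(glance(presso), file.path(out_dir, "mr_presso.tsv"))
    write_tsv_plain(loo, file.path(out_dir, "mr_leave_one_out.tsv"))
    write_tsv_plain(glance(fs), file.path(out_dir, "mr_instruments.tsv"))
    res$mr <- list(panel = panel, presso = presso, loo = loo, strength = fs)
  }

  if ("network_mr" %in% stages) {
    nm <- run_network_mr(
      gw$exp_exposure, gw$exp_mediator, gw$exp_outcome,
      gw$med_mediator, gw$med_exposure, gw$med_outcome
    )
    write_tsv_plain(tidy(nm), file.path(out_dir, "network_mr_edges.tsv"))
    write_tsv_plain(glance(nm), file.path(out_dir, "network_mr_mediation.tsv"))
    res$network_mr <- nm
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- tibble::tibble(
    file = basename(files), md5 = unname(tools::md5sum(files))
  )
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}
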