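#' Default run configuration
#'
#' Single source of truth for every tunable of the pipeline. Defaults follow
#' the published protocol where one exists: segmentation cutoff SUV 2.5,
#' quantization bin width 0.4 over the 0-25 SUV window with 64 levels, k = 3
#' clusters, alpha 0.05 with the feature count as Bonferroni denominator.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    segmentation = list(cutoff = 2.5),
    quantization = list(bin_width = 0.4, range_min = 0, range_max = 25,
                        n_levels = 64L),
    clustering = list(k = 3L, linkage = "ward.D2", min_cluster_size = 2L),
    statistics = list(alpha = 0.05, bonferroni_denominator = 109L),
    simulate = list(n_per_archetype = c(10L, 25L, 37L), jitter_sd = 0.15),
    seed = 20090701L), class = "run_config")
}

#' Read / write a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path.
#' @return [read_config]: a `run_config`; [write_config]: `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(unclass(default_config()), cfg)
  validate_config(structure(out, class = "run_config"))
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  if (config$clustering$k < 2L)
    stopf("config error: clustering.k must be >= 2, got %d", config$clustering$k)
  if (config$quantization$bin_width <= 0)
    stopf("config error: quantization.bin_width must be > 0")
  if (config$segmentation$cutoff <= 0)
    stopf("config error: segmentation.cutoff must be > 0")
  if (config$statistics$alpha <= 0 || config$statistics$alpha >= 1)
    stopf("config error: statistics.alpha must lie in (0, 1)")
  config
}

#' Extract features for a list of volumes
#'
#' Segments each volume at the configured SUV cutoff and extracts the
#' 109-feature vector.
#'
#' @param volumes list of [suv_volume].
#' @param config a `run_config` (default [default_config]).
#' @return Numeric matrix, one row per volume, 109 registry columns.
#' @export
extract_cohort_features <- function(volumes, config = default_config()) {
  qcfg <- config$quantization
  rows <- lapply(seq_along(volumes), function(i) {
    seg <- segment_fixed_threshold(volumes[[i]], cutoff = config$segmentation$cutoff)
    extract_all_features(volumes[[i]], seg$mask,
                         config = list(bin_width = qcfg$bin_width,
                                       range_min = qcfg$range_min,
                                       range_max = qcfg$range_max,
                                       n_levels = qcfg$n_levels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(volumes)
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Chains simulate -> segment -> extract -> cluster -> associate and writes a
#' report directory: the feature table, cluster assignment, correlogram and
#' heat-map matrices (CSV) with rendered PNGs, per-cluster feature summaries,
#' association tables (chi-square, odds ratios, log-rank, Cox) and a
#' machine-readable `summary.json`. Deterministic for a fixed `config$seed`.
#'
#' @param config a `run_config`.
#' @param out_dir report directory (created if missing).
#' @param render_plots write PNG artifacts (default TRUE).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "petradiomics-report",
                         render_plots = TRUE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- stage("simulate", make_cohort(
    n_per_archetype = config$simulate$n_per_archetype,
    jitter_sd = config$simulate$jitter_sd, seed = config$seed))
  cohort <- sim$cohort

  feats <- stage("extract", extract_cohort_features(sim$volumes, config))
  rownames(feats) <- cohort$patient_id
  utils::write.csv(cbind(patient_id = cohort$patient_id, as.data.frame(feats)),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  z <- stage("standardize", zscore_features(feats))
  cg <- stage("correlogram", correlogram(
    feats, alpha = config$statistics$alpha,
    correction_denominator = config$statistics$bonferroni_denominator))
  utils::write.csv(as.data.frame(cg$r), file.path(out_dir, "correlation_matrix.csv"),
                   row.names = TRUE)

  cl <- stage("cluster", hierarchical_clusters(
    z, k = config$clustering$k, linkage = config$clustering$linkage,
    min_cluster_size = config$clustering$min_cluster_size))
  clusters_df <- data.frame(patient_id = cohort$patient_id,
                            archetype = cohort$archetype,
                            cluster = ifelse(is.na(cl$label), "OUTLIER",
                                             as.character(cl$label)))
  utils::write.csv(clusters_df, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)

  rep_feats <- c("SUV_max", "SUV_mean", "MTV", "TLG", "CV",
                 "NL_Entropy^GLCM", "NL_Homogeneity^GLCM", "ZP^GLSZM",
                 "Skewness")
  summ <- stage("cluster_summary",
                cluster_feature_summary(feats, cl, feature_names = rep_feats))
  utils::write.csv(summ, file.path(out_dir, "cluster_feature_summary.csv"),
                   row.names = FALSE)

  ok <- !is.na(cl$label)
  cohort_cl <- cbind(cohort[ok, ], cluster = cl$label[ok])
  assoc <- stage("associate", {
    chis <- lapply(c(er = "er", pgr = "pgr", her2 = "her2",
                     ki67_high = "ki67_high", pcr = "pcr"),
                   function(v) proportions_test(cohort_cl$cluster, cohort_cl[[v]]))
    or_rows <- lapply(sort(unique(cohort_cl$cluster)), function(cc) {
      expo <- cohort_cl$cluster == cc
      tab <- contingency_2x2(sum(expo & cohort_cl$pcr == 1),
                             sum(expo & cohort_cl$pcr == 0),
                             sum(!expo & cohort_cl$pcr == 1),
                             sum(!expo & cohort_cl$pcr == 0))
      res <- tryCatch(odds_ratio_2x2(tab), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(comparison = sprintf("cluster %d vs others", cc),
                 or = res$or, ci_lower = res$ci_lower,
                 ci_upper = res$ci_upper, p = res$p, method = res$method)
    })
    km <- km_logrank(cohort_cl, group = cohort_cl$cluster)
    list(chisq = chis, or_table = do.call(rbind, or_rows), km = km)
  })
  utils::write.csv(assoc$or_table, file.path(out_dir, "pcr_odds_ratios.csv"),
                   row.names = FALSE)

  if (render_plots) {
    grDevices::png(file.path(out_dir, "heatmap.png"), width = 900, height = 700)
    plot_radiomics_heatmap(z, cl)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "correlogram.png"), width = 800, height = 800)
    plot_correlogram(cg)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "km_curves.png"), width = 800, height = 600)
    graphics::plot(assoc$km$fit, col = seq_len(config$clustering$k), lwd = 2,
                   xlab = "months", ylab = "disease-free survival")
    grDevices::dev.off()
  }

  summary <- list(
    n_patients = nrow(cohort),
    n_features = ncol(feats),
    cluster_sizes = as.list(table(cl$label)),
    n_outliers = cl$n_outliers,
    significant_feature_pairs = sum(cg$significant, na.rm = TRUE) / 2,
    pcr_rate_by_cluster = lapply(split(cohort_cl$pcr, cohort_cl$cluster), mean),
    logrank_p = assoc$km$logrank_p,
    chisq_p = lapply(assoc$chisq, function(x) x$p),
    seed = config$seed)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(summary)
}
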