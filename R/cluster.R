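#' Z-score standardization of a cohort feature matrix
#'
#' Centers every feature column to mean 0 and scales to population SD 1.
#' Zero-variance columns carry no clustering information and are dropped with
#' a warning.
#'
#' @param features numeric matrix or data.frame, one row per patient, one
#'   column per feature.
#' @return Numeric matrix with attribute `dropped` naming any removed
#'   constant columns.
#' @examples
#' zscore_features(cbind(a = c(1, 2, 3), b = c(5, 6, 10)))
#' @export
zscore_features <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stopf("feature matrix must be numeric")
  if (nrow(x) < 2L) stopf("need at least 2 patients to standardize")
  if (anyNA(x)) stopf("feature matrix contains missing values")
  n <- nrow(x)
  mu <- colMeans(x)
  sdev <- sqrt(colSums(sweep(x, 2, mu)^2) / n)  # population SD
  const <- sdev == 0
  if (all(const)) stopf("all feature columns are constant")
  if (any(const)) {
    warning(sprintf("dropping %d zero-variance feature column(s): %s",
                    sum(const),
                    paste(colnames(x)[const], collapse = ", ")),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]; sdev <- sdev[!const]
  }
  z <- sweep(sweep(x, 2, mu), 2, sdev, `/`)
  attr(z, "dropped") <- colnames(features)[const]
  z
}

#' Pearson correlogram of the feature matrix
#'
#' Pairwise Pearson correlations with two-sided p-values, a Bonferroni
#' significance mask and a hierarchical feature ordering of the
#' correlation-distance matrix (1 - r, complete linkage). The default
#' correction denominator is the feature count, giving the conventional
#' 0.05/109 = 4.6e-4 threshold for the full registry.
#'
#' @param features numeric matrix, patients x features.
#' @param alpha familywise significance level (default 0.05).
#' @param correction_denominator Bonferroni denominator (default: number of
#'   features).
#' @return Object of class `correlogram_result`: `r`, `p`, `significant`
#'   (logical mask), `order` (feature ordering), `threshold`.
#' @export
correlogram <- function(features, alpha = 0.05,
                        correction_denominator = ncol(features)) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3L) stopf("need at least 3 patients for correlation inference")
  sdev <- apply(x, 2, stats::sd)
  const <- sdev == 0
  r <- suppressWarnings(stats::cor(x))
  # two-sided p from the t transform of r
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  r[const, ] <- NA; r[, const] <- NA
  p[const, ] <- NA; p[, const] <- NA
  diag(r) <- ifelse(const, NA_real_, 1)
  threshold <- alpha / correction_denominator
  sig <- !is.na(p) & p < threshold
  diag(sig) <- FALSE
  d <- 1 - r
  d[is.na(d)] <- 2  # constant features sort to the periphery
  ord <- stats::hclust(stats::as.dist(d), method = "complete")$order
  structure(list(r = r, p = p, significant = sig, order = ord,
                 threshold = threshold, alpha = alpha,
                 correction_denominator = correction_denominator),
            class = "correlogram_result")
}

#' @export
print.correlogram_result <- function(x, ...) {
  m <- ncol(x$r)
  cat(sprintf("Correlogram: %d features, %d significant pairs at p < %.3g (Bonferroni %g/%d)\n",
              m, sum(x$significant, na.rm = TRUE) / 2, x$threshold,
              x$alpha, x$correction_denominator))
  invisible(x)
}

#' Unsupervised hierarchical clustering of patients with outlier ejection
#'
#' Agglomerative clustering of the standardized feature matrix (Euclidean
#' distance) cut to `k` clusters. Patients falling in branches smaller than
#' `min_cluster_size` at that cut are ejected as outliers and the tree is
#' rebuilt and re-cut among the remaining patients, mirroring the practice of
#' excluding single cases whose texture fits no phenotype group.
#'
#' Ward linkage is the default: its within-cluster-variance objective matches
#' the z-scored Euclidean feature space and separates planted phenotypes that
#' complete linkage chains together; complete and average linkage remain
#' available.
#'
#' @param z standardized feature matrix (from [zscore_features]).
#' @param k number of clusters (default 3).
#' @param linkage agglomeration method: "ward.D2" (default), "complete" or
#'   "average".
#' @param min_cluster_size smallest admissible cluster (default 2).
#' @return Object of class `cluster_assignment`: `label` (integer per
#'   patient, `NA` = outlier), `k`, `linkage`, `n_outliers`,
#'   `patient_order`, `feature_order` (dendrogram orderings for heat-map
#'   rendering).
#' @export
hierarchical_clusters <- function(z, k = 3L, linkage = c("ward.D2", "complete", "average"),
                                  min_cluster_size = 2L) {
  linkage <- match.arg(linkage)
  z <- as.matrix(z)
  n <- nrow(z)
  if (k < 1L) stopf("`k` must be >= 1")
  if (n < k + 1L) stopf("need more than k = %d patients, got %d", k, n)
  active <- seq_len(n)
  label <- rep(NA_integer_, n)
  hc_final <- NULL
  repeat {
    hc <- stats::hclust(stats::dist(z[active, , drop = FALSE]), method = linkage)
    cut <- stats::cutree(hc, k = k)
    sizes <- tabulate(cut, nbins = k)
    small <- which(sizes < min_cluster_size)
    if (!length(small)) {
      hc_final <- hc
      label[active] <- cut
      break
    }
    out <- active[cut %in% small]
    active <- setdiff(active, out)
    if (length(active) < k + 1L)
      stopf("outlier ejection left fewer than k + 1 patients")
  }
  # stable cluster numbering: order clusters by first patient index
  firsts <- vapply(seq_len(k), function(cc) min(which(label == cc)), numeric(1))
  label <- match(label, order(firsts))
  feat_ord <- if (ncol(z) > 1L)
    stats::hclust(stats::dist(t(z)), method = linkage)$order else 1L
  structure(list(label = label, k = as.integer(k), linkage = linkage,
                 n_outliers = sum(is.na(label)),
                 patient_order = active[hc_final$order],
                 feature_order = feat_ord),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(x$label)
  cat(sprintf("Hierarchical clustering (%s linkage): k = %d, sizes %s, %d outlier(s)\n",
              x$linkage, x$k, paste(sizes, collapse = "/"), x$n_outliers))
  invisible(x)
}

#' Per-cluster feature summaries with Kruskal-Wallis tests
#'
#' Median and range of each requested feature per cluster, with a
#' Kruskal-Wallis rank test (tie-corrected) across clusters. Outliers
#' (NA labels) are excluded.
#'
#' @param features numeric matrix or data.frame, patients x features.
#' @param assignment a `cluster_assignment` (or integer label vector).
#' @param feature_names columns to summarize (default: all).
#' @return data.frame with one row per feature: per-cluster
#'   `median_<c>`, `min_<c>`, `max_<c>` columns, `kw_statistic`, `kw_p`.
#' @export
cluster_feature_summary <- function(features, assignment,
                                    feature_names = colnames(features)) {
  label <- if (inherits(assignment, "cluster_assignment")) assignment$label
           else as.integer(assignment)
  x <- as.matrix(features)
  if (length(label) != nrow(x)) stopf("assignment length does not match patients")
  keep <- !is.na(label)
  x <- x[keep, , drop = FALSE]; label <- label[keep]
  cl <- sort(unique(label))
  if (length(cl) < 2L) stopf("need at least 2 clusters with members")
  rows <- lapply(feature_names, function(f) {
    v <- x[, f]
    stats_per <- lapply(cl, function(cc) {
      vi <- v[label == cc]
      c(median = stats::median(vi), min = min(vi), max = max(vi))
    })
    if (length(unique(v)) == 1L) {
      # all observations tied: no rank variation, H = 0 by convention
      kw <- list(statistic = 0, p.value = 1)
    } else {
      kw <- stats::kruskal.test(v, factor(label))
    }
    row <- c(unlist(stats_per), kw_statistic = unname(kw$statistic),
             kw_p = kw$p.value)
    names(row)[seq_len(3 * length(cl))] <-
      paste0(rep(c("median_", "min_", "max_"), length(cl)),
             rep(cl, each = 3))
    row
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(feature = feature_names, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Radiomics heat map
#'
#' Renders the standardized feature matrix with patients and features in
#' their dendrogram orders (red-to-green through black, the conventional
#' radiomics coloring).
#'
#' @param z standardized feature matrix.
#' @param assignment a `cluster_assignment` for the orderings.
#' @param ... passed to [graphics::image].
#' @return Invisibly, the reordered matrix that was drawn.
#' @export
plot_radiomics_heatmap <- function(z, assignment, ...) {
  z <- as.matrix(z)
  po <- assignment$patient_order
  fo <- assignment$feature_order
  m <- z[po, fo, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("red", "black", "green"))(64)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(pmax(pmin(m, 3), -3)), col = pal,
                  xlab = "texture features", ylab = "patients",
                  main = "Radiomics heat map", ...)
  invisible(m)
}

#' Correlogram plot
#' @param x a `correlogram_result`.
#' @param ... passed to [graphics::image].
#' @return Invisibly, the reordered correlation matrix.
#' @export
plot_correlogram <- function(x, ...) {
  stopifnot(inherits(x, "correlogram_result"))
  m <- x$r[x$order, x$order]
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = c(-1, 1), col = pal,
                  xlab = "", ylab = "", main = "Feature correlogram", ...)
  invisible(m)
}
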