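# Feature formulas per matrix family. All probability-form features are
# computed from the normalized matrix (counts / total), the "NL_" (normalized)
# convention; entropies are in bits (log base 2).

# Core Haralick-style statistics of a symmetric co-occurrence probability
# matrix. Gray-level weights are the row/column indices.
haralick_core <- function(p) {
  Ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  absdiff <- abs(i - j)
  # distributions of i+j and |i-j|
  psum <- vapply(2:(2 * Ng), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(Ng - 1), function(k) sum(p[absdiff == k]), numeric(1))
  ksum <- 2:(2 * Ng); kdiff <- 0:(Ng - 1)
  sum_mean <- sum(ksum * psum)
  diff_mean <- sum(kdiff * pdiff)
  hxy <- shannon_entropy(p)
  hx <- shannon_entropy(px); hy <- shannon_entropy(py)
  pxy <- outer(px, py)
  pos <- pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- -sum(pxy[pos] * log2(pxy[pos]))
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  mu <- mux  # symmetric matrix: mux == muy
  c(Energy = sum(p^2),
    Entropy = hxy,
    Dissimilarity = diff_mean,
    Contrast = sum(p * (i - j)^2),
    Homogeneity = sum(p / (1 + absdiff)),
    IDM = sum(p / (1 + (i - j)^2)),
    InverseVariance = sum(p[absdiff > 0] / (i - j)[absdiff > 0]^2),
    Correlation = corr,
    Autocorrelation = sum(i * j * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    MaxProbability = max(p),
    Variance = sum((i - mu)^2 * p),
    SumMean = sum_mean,
    SumVariance = sum((ksum - sum_mean)^2 * psum),
    SumEntropy = shannon_entropy(psum),
    DiffMean = diff_mean,
    DiffVariance = sum((kdiff - diff_mean)^2 * pdiff),
    DiffEntropy = shannon_entropy(pdiff),
    IMC1 = imc1,
    IMC2 = imc2)
}

#' GLCM features
#'
#' The 22 co-occurrence features of the registry, including
#' `NL_Entropy^GLCM = -sum p log2 p`, `NL_Homogeneity^GLCM = sum p/(1+|i-j|)`
#' and `NL_Dissimilarity^GLCM = sum p |i-j|`, all computed from the
#' probability-normalized symmetric matrix.
#'
#' @param m a `glcm` from [compute_glcm].
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  h <- haralick_core(m$p)
  names(h) <- paste0(names(h), "^GLCM")
  names(h)[names(h) == "Entropy^GLCM"] <- "NL_Entropy^GLCM"
  names(h)[names(h) == "Homogeneity^GLCM"] <- "NL_Homogeneity^GLCM"
  names(h)[names(h) == "Dissimilarity^GLCM"] <- "NL_Dissimilarity^GLCM"
  h
}

#' GLRLM features
#' @param m a `glrlm` from [compute_glrlm].
#' @return Named numeric vector of 11 run-length features.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  r <- m$r
  Nr <- sum(r)
  i <- row(r); l <- col(r)
  ri <- rowSums(r); rl <- colSums(r)
  iv <- seq_len(nrow(r)); lv <- seq_len(ncol(r))
  out <- c(
    SRE = sum(rl / lv^2) / Nr,
    LRE = sum(rl * lv^2) / Nr,
    GLN = sum(ri^2) / Nr,
    RLN = sum(rl^2) / Nr,
    RP = Nr / sum(l * r),
    LGRE = sum(ri / iv^2) / Nr,
    HGRE = sum(ri * iv^2) / Nr,
    SRLGE = sum(r / (i^2 * l^2)) / Nr,
    SRHGE = sum(r * i^2 / l^2) / Nr,
    LRLGE = sum(r * l^2 / i^2) / Nr,
    LRHGE = sum(r * i^2 * l^2) / Nr)
  names(out) <- paste0(names(out), "^GLRLM")
  out
}

#' GLSZM features
#'
#' Includes `ZP^GLSZM = n_zones / n_voxels` and the intensity-weighted
#' emphases, e.g. `HILZE^GLSZM = sum z(i,s) i^2 s^2 / n_zones`.
#'
#' @param m a `glszm` from [compute_glszm].
#' @return Named numeric vector of 11 size-zone features.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "glszm"))
  z <- m$z
  Nz <- m$n_zones
  i <- row(z); s <- col(z)
  zi <- rowSums(z); zs <- colSums(z)
  iv <- seq_len(nrow(z)); sv <- seq_len(ncol(z))
  out <- c(
    SZE = sum(zs / sv^2) / Nz,
    LZE = sum(zs * sv^2) / Nz,
    GLN = sum(zi^2) / Nz,
    ZSN = sum(zs^2) / Nz,
    ZP = Nz / m$n_voxels,
    LIZE = sum(zi / iv^2) / Nz,
    HIZE = sum(zi * iv^2) / Nz,
    LISZE = sum(z / (i^2 * s^2)) / Nz,
    HISZE = sum(z * i^2 / s^2) / Nz,
    LILZE = sum(z * s^2 / i^2) / Nz,
    HILZE = sum(z * i^2 * s^2) / Nz)
  names(out) <- paste0(names(out), "^GLSZM")
  out
}

#' NGTDM features
#'
#' The five neighborhood gray-tone difference statistics (coarseness,
#' contrast, busyness, complexity, strength); coarseness carries an epsilon
#' guard against a vanishing denominator.
#'
#' @param m an `ngtdm` from [compute_ngtdm].
#' @param eps denominator guard (default 1e-6).
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(m, eps = 1e-6) {
  stopifnot(inherits(m, "ngtdm"))
  occ <- which(m$n_i > 0)
  p <- m$p_i; s <- m$s_i
  Ngp <- length(occ)
  N <- m$n_valid
  coarseness <- 1 / (eps + sum(p * s))
  if (Ngp > 1) {
    pi_ <- p[occ]; ii <- occ
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (Ngp * (Ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
    busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
    psi <- p[occ] * s[occ]
    psum <- outer(pi_, pi_, `+`)
    complexity <- sum(abs(outer(ii, ii, `-`)) * outer(psi, psi, `+`) / psum) / N
    strength <- sum(psum * dif2) / (eps + sum(s))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(`Coarseness^NGTDM` = coarseness, `Contrast^NGTDM` = contrast,
    `Busyness^NGTDM` = busyness, `Complexity^NGTDM` = complexity,
    `Strength^NGTDM` = strength)
}

#' NGLDM features
#' @param m an `ngldm` from [compute_ngldm].
#' @return Named numeric vector of 6 dependence features (small/large number
#'   emphasis, gray-level and dependence-count nonuniformity, second moment,
#'   entropy).
#' @export
ngldm_features <- function(m) {
  stopifnot(inherits(m, "ngldm"))
  d <- m$d
  N <- sum(d)
  kv <- 0:26  # dependence counts
  di <- rowSums(d); dk <- colSums(d)
  p <- d / N
  out <- c(
    SNE = sum(dk / (kv + 1)^2) / N,
    LNE = sum(dk * (kv + 1)^2) / N,
    GLN = sum(di^2) / N,
    NN = sum(dk^2) / N,
    SecondMoment = sum(p^2),
    Entropy = shannon_entropy(p))
  names(out) <- paste0(names(out), "^NGLDM")
  out
}

#' Texture spectrum features
#'
#' Symmetry and orientation statistics of the ternary texture-unit spectrum:
#' black-white symmetry (invariance under swapping "less" and "greater"),
#' geometric symmetry (invariance under point reflection of the
#' neighborhood), degree of direction (invariance under axis transpositions),
#' central symmetry of opposite neighbor pairs, the mean per-axis flatness
#' and its anisotropy, the overall fraction of "equal" codes, and the
#' spectrum entropy.
#'
#' @param ts a `texture_spectrum` from [compute_texture_spectrum].
#' @return Named numeric vector of 8 features.
#' @export
texture_spectrum_features <- function(ts) {
  stopifnot(inherits(ts, "texture_spectrum"))
  codes <- ts$codes
  n <- nrow(codes)
  spec_dist <- function(units_a, units_b) {
    ta <- table(units_a); tb <- table(units_b)
    u <- union(names(ta), names(tb))
    a <- as.numeric(ta[u]); a[is.na(a)] <- 0
    b <- as.numeric(tb[u]); b[is.na(b)] <- 0
    sum(abs(a - b)) / (2 * n)
  }
  base_units <- unit_strings(codes)
  inv_codes <- 2L - codes  # swap less <-> greater
  bws <- 1 - spec_dist(base_units, unit_strings(inv_codes))
  opp <- opposite_permutation()
  gs <- 1 - spec_dist(base_units, unit_strings(codes[, opp, drop = FALSE]))
  swaps <- list(axis_swap_permutation(1, 2), axis_swap_permutation(1, 3),
                axis_swap_permutation(2, 3))
  dd <- 1 - mean(vapply(swaps, function(pm)
    spec_dist(base_units, unit_strings(codes[, pm, drop = FALSE])), numeric(1)))
  # central symmetry: code(o) agrees with the inverted code at -o
  half <- which(seq_len(26L) < opp)
  cs <- mean(codes[, half, drop = FALSE] == 2L - codes[, opp[half], drop = FALSE])
  # per-axis flatness: both axis neighbors equal to the center
  offs <- offsets26()
  ms_ax <- vapply(1:3, function(ax) {
    k <- which(offs[, ax] != 0 & rowSums(abs(offs)) == 1)
    mean(codes[, k[1]] == 1L & codes[, k[2]] == 1L)
  }, numeric(1))
  pspec <- as.numeric(ts$spectrum) / n
  c(`BWS^TS` = bws, `GS^TS` = gs, `DD^TS` = dd, `CS^TS` = cs,
    `MicroStructure^TS` = mean(ms_ax),
    `Anisotropy^TS` = max(ms_ax) - min(ms_ax),
    `EqualFraction^TS` = mean(codes == 1L),
    `Entropy^TS` = shannon_entropy(pspec))
}

#' Texture feature coding features
#' @param tfc a `tfc_volume` from [compute_tfc].
#' @return Named numeric vector of 8 statistics of the code histogram.
#' @export
tfc_features <- function(tfc) {
  stopifnot(inherits(tfc, "tfc_volume"))
  codes <- tfc$code[tfc$coded_idx]
  p <- tabulate(codes + 1L, nbins = 40L) / length(codes)
  cv <- 0:39
  mu <- sum(cv * p)
  out <- c(
    MeanCode = mu,
    Variance = sum((cv - mu)^2 * p),
    MeanConvergence = sum(abs(cv - mu) * p),
    CodeEntropy = shannon_entropy(p),
    CodeEnergy = sum(p^2),
    Homogeneity = p[1],
    Coarseness = 1 / (1 + mu),
    MaxCodeFraction = max(p))
  names(out) <- paste0(names(out), "^TFC")
  out
}

#' TFCCM features
#' @param m a `tfccm` from [compute_tfccm].
#' @return Named numeric vector of 20 co-occurrence statistics of the TFC
#'   codes, including `Entropy^TFCCM`.
#' @export
tfccm_features <- function(m) {
  stopifnot(inherits(m, "tfccm"))
  h <- haralick_core(m$p)
  h <- h[!names(h) %in% c("InverseVariance", "Autocorrelation")]
  names(h) <- paste0(names(h), "^TFCCM")
  h
}

#' SUV histogram statistics
#'
#' First-order statistics of the raw (unquantized) SUVs of the masked voxels,
#' plus the conventional volumetric indices: MTV (voxel count times voxel
#' volume, cm3), TLG = SUVmean x MTV, and CV = population SD / SUVmean.
#' Skewness and kurtosis use population moments and are 0 by convention on
#' constant input.
#'
#' @param volume a [suv_volume].
#' @param mask a [roi_mask].
#' @param levels optional integer vector of quantized gray levels of the
#'   masked voxels (for the histogram entropy/uniformity features); when
#'   `NULL` the default fixed-bin-width quantizer is applied internally.
#' @return Named numeric vector of 18 features.
#' @export
suv_statistics <- function(volume, mask, levels = NULL) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "roi_mask"))
  idx <- which(mask$flags)
  if (length(idx) == 0L) stopf("empty mask")
  x <- volume$values[idx]
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - mu)^3) / n / s^3 else 0
  kurt <- if (s > 0) sum((x - mu)^4) / n / s^4 else 0
  if (is.null(levels)) {
    lev <- pmin(pmax(floor(x / 0.4) + 1, 1), 64)
  } else lev <- levels
  ph <- tabulate(lev, nbins = max(lev)) / n
  mtv <- n * prod(volume$spacing) / 1000
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  c(SUV_max = max(x), SUV_min = min(x), SUV_mean = mu, SUV_median = q[2],
    SUV_sd = s, SUV_var = v, SUV_range = max(x) - min(x),
    SUV_q1 = q[1], SUV_q3 = q[3], SUV_iqr = q[3] - q[1],
    SUV_rms = sqrt(mean(x^2)),
    CV = if (mu > 0) s / mu else 0,
    Skewness = skew, Kurtosis = kurt,
    HistEntropy = shannon_entropy(ph), HistUniformity = sum(ph^2),
    MTV = mtv, TLG = mu * mtv)
}
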