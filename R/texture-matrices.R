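# Texture matrix construction. Every matrix is lattice-based and aggregated
# over directions: GLCM over all 26 offsets (both orientations -> symmetric),
# GLRLM over the 13 unique directions, zones/neighborhoods 26-connected.
# Neighborhoods are truncated at the mask boundary: only in-mask neighbors
# are ever counted, so background never contaminates a feature.

# ---- GLCM ------------------------------------------------------------------

# Symmetric co-occurrence counts of an integer-labelled array over the 13
# unique offsets at `distance`, restricted to labelled (non-NA) voxels.
cooccurrence_counts <- function(levels, Ng, distance = 1L) {
  dims <- dim(levels)
  counts <- numeric(Ng * Ng)
  offs <- offsets13() * distance
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(dims, offs[k, ])
    la <- levels[pr$a]; lb <- levels[pr$b]
    ok <- !is.na(la) & !is.na(lb)
    if (!any(ok)) next
    la <- la[ok]; lb <- lb[ok]
    counts <- counts + tabulate(la + Ng * (lb - 1L), nbins = Ng * Ng) +
      tabulate(lb + Ng * (la - 1L), nbins = Ng * Ng)
  }
  matrix(counts, Ng, Ng)
}

#' Gray level co-occurrence matrix (GLCM)
#'
#' Counts co-occurring gray-level pairs over all 26 lattice offsets at the
#' given distance (both orientations, giving a symmetric matrix), restricted
#' to in-mask voxel pairs, then normalizes to probabilities.
#'
#' @param q a `quantized_roi`.
#' @param distance lattice step between paired voxels (default 1).
#' @return Object of class `glcm`: `p` (Ng x Ng probabilities), `distance`,
#'   `n_pairs` (directed pair count).
#' @export
compute_glcm <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_roi"))
  cnt <- cooccurrence_counts(q$levels, q$Ng, distance)
  total <- sum(cnt)
  if (total == 0) stopf("no in-mask voxel pairs at distance %d", distance)
  structure(list(p = cnt / total, distance = as.integer(distance),
                 n_pairs = total),
            class = "glcm")
}

# ---- GLRLM -----------------------------------------------------------------

#' Gray level run-length matrix (GLRLM)
#'
#' Runs of collinear equal-level voxels are counted separately along each of
#' the 13 unique lattice directions and aggregated by summation. A run stops
#' at the mask boundary or at a level change.
#'
#' @param q a `quantized_roi`.
#' @return Object of class `glrlm`: `r` (Ng x Rmax counts), `n_voxels`,
#'   `n_directions`.
#' @export
compute_glrlm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  dims <- dim(q$levels)
  idx <- q$mask_idx
  lev <- q$levels[idx]
  coords <- arrayInd(idx, dims)
  offs <- offsets13()
  M <- max(dims) + 2L
  run_level <- integer(0); run_len <- integer(0)
  for (k in seq_len(13L)) {
    o <- offs[k, ]
    j0 <- which(o != 0L)[1]
    s <- coords[, j0] * o[j0]
    base <- coords - outer(s, o)
    key <- (base[, 1] + M) + (base[, 2] + M) * (3 * M) +
      (base[, 3] + M) * (9 * M * M)
    ord <- order(key, s)
    ks <- key[ord]; ss <- s[ord]; ls <- lev[ord]
    brk <- c(TRUE, ks[-1] != ks[-length(ks)] | ss[-1] != ss[-length(ss)] + 1L |
               ls[-1] != ls[-length(ls)])
    run_id <- cumsum(brk)
    run_level <- c(run_level, ls[brk])
    run_len <- c(run_len, tabulate(run_id))
  }
  rmax <- max(run_len)
  r <- matrix(0, q$Ng, rmax)
  tab <- table(factor(run_level, levels = seq_len(q$Ng)),
               factor(run_len, levels = seq_len(rmax)))
  r[] <- as.numeric(tab)
  structure(list(r = r, n_voxels = length(idx), n_directions = 13L),
            class = "glrlm")
}

# ---- GLSZM -----------------------------------------------------------------

#' Gray level size zone matrix (GLSZM)
#'
#' Zones are maximal 26-connected sets of in-mask voxels sharing a gray level.
#'
#' @param q a `quantized_roi`.
#' @return Object of class `glszm`: `z` (Ng x Smax zone counts), `n_zones`,
#'   `n_voxels`.
#' @export
compute_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  idx <- q$mask_idx
  if (length(idx) == 0L) stopf("empty quantized ROI")
  comp <- components26(idx, dim(q$levels), values = q$levels)
  sizes <- tabulate(comp)
  lev_of_zone <- q$levels[idx][match(seq_along(sizes), comp)]
  smax <- max(sizes)
  z <- matrix(0, q$Ng, smax)
  tab <- table(factor(lev_of_zone, levels = seq_len(q$Ng)),
               factor(sizes, levels = seq_len(smax)))
  z[] <- as.numeric(tab)
  structure(list(z = z, n_zones = length(sizes), n_voxels = length(idx)),
            class = "glszm")
}

# ---- NGTDM -----------------------------------------------------------------

#' Neighborhood gray tone difference matrix (NGTDM)
#'
#' For each gray level, the summed absolute deviation of its voxels from the
#' mean level of their 26-neighborhood (in-mask neighbors only), plus the
#' level occurrence probabilities. Only voxels with at least one valid
#' neighbor contribute.
#'
#' @param q a `quantized_roi`.
#' @return Object of class `ngtdm`: vectors `p_i`, `s_i`, `n_i` indexed by
#'   gray level, and `n_valid` (contributing voxel count).
#' @export
compute_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  nbr <- neighbor_matrix(q$levels, q$mask_idx)
  lev <- q$levels[q$mask_idx]
  nn <- rowSums(!is.na(nbr))
  keep <- nn > 0
  if (!any(keep)) stopf("no voxel has an in-mask neighbor")
  abar <- rowMeans(nbr, na.rm = TRUE)[keep]
  lv <- lev[keep]
  dev <- abs(lv - abar)
  Ng <- q$Ng
  n_i <- tabulate(lv, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(i) sum(dev[lv == i]), numeric(1))
  structure(list(p_i = n_i / sum(n_i), s_i = s_i, n_i = n_i,
                 n_valid = sum(keep)),
            class = "ngtdm")
}

# ---- NGLDM -----------------------------------------------------------------

#' Neighboring gray level dependence matrix (NGLDM)
#'
#' A neighbor is dependent when its level differs from the center by at most
#' the tolerance `a`. Counts voxels by (gray level, number of dependent
#' neighbors); voxels with no in-mask neighbor are excluded.
#'
#' @param q a `quantized_roi`.
#' @param a dependence tolerance in gray levels (default 0).
#' @return Object of class `ngldm`: `d` (Ng x 27 counts, dependence 0..26),
#'   `n_valid`, `a`.
#' @export
compute_ngldm <- function(q, a = 0L) {
  stopifnot(inherits(q, "quantized_roi"))
  nbr <- neighbor_matrix(q$levels, q$mask_idx)
  lev <- q$levels[q$mask_idx]
  nn <- rowSums(!is.na(nbr))
  keep <- nn > 0
  if (!any(keep)) stopf("no voxel has an in-mask neighbor")
  dep <- rowSums(abs(nbr - lev) <= a, na.rm = TRUE)[keep]
  lv <- lev[keep]
  d <- matrix(0, q$Ng, 27L)
  tab <- table(factor(lv, levels = seq_len(q$Ng)),
               factor(dep, levels = 0:26))
  d[] <- as.numeric(tab)
  structure(list(d = d, n_valid = sum(keep), a = as.integer(a)),
            class = "ngldm")
}

# ---- Texture spectrum ------------------------------------------------------

# Ternary comparison codes of every masked voxel against its 26 neighbors:
# 0 = neighbor less than center, 1 = equal, 2 = greater; NA = neighbor
# outside mask/grid. Rows follow q$mask_idx, columns follow offsets26().
ternary_codes <- function(q) {
  nbr <- neighbor_matrix(q$levels, q$mask_idx)
  lev <- q$levels[q$mask_idx]
  codes <- matrix(NA_integer_, nrow(nbr), 26L)
  codes[] <- 1L + sign(nbr - lev)
  codes
}

offset_key <- function(o) (o[, 1] + 1) + 3 * (o[, 2] + 1) + 9 * (o[, 3] + 1)

# index permutation sending each offset to its negation
opposite_permutation <- function() {
  o <- offsets26()
  match(offset_key(-o), offset_key(o))
}

axis_swap_permutation <- function(ax1, ax2) {
  o <- offsets26()
  swapped <- o
  swapped[, c(ax1, ax2)] <- o[, c(ax2, ax1)]
  match(offset_key(swapped), offset_key(o))
}

unit_strings <- function(codes) {
  do.call(paste0, lapply(seq_len(ncol(codes)), function(k) codes[, k]))
}

#' Texture spectrum
#'
#' Each voxel's texture unit codes its 26 neighbors as less than, equal to or
#' greater than the center; the spectrum is the histogram of units. Units are
#' built from interior voxels (all 26 neighbors in-mask) when any exist,
#' otherwise from all voxels with at least one valid neighbor with missing
#' neighbors coded as "equal".
#'
#' @param q a `quantized_roi`.
#' @return Object of class `texture_spectrum`: `spectrum` (named unit counts),
#'   `codes` (voxel x 26 ternary codes of the contributing voxels),
#'   `n_units`, `interior` (whether only interior voxels were used).
#' @export
compute_texture_spectrum <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  codes <- ternary_codes(q)
  valid <- rowSums(!is.na(codes))
  if (!any(valid > 0)) stopf("no voxel has an in-mask neighbor")
  interior <- valid == 26L
  if (any(interior)) {
    codes <- codes[interior, , drop = FALSE]
    used_interior <- TRUE
  } else {
    codes <- codes[valid > 0, , drop = FALSE]
    codes[is.na(codes)] <- 1L
    used_interior <- FALSE
  }
  units <- unit_strings(codes)
  spec <- table(units)
  structure(list(spectrum = spec, codes = codes, n_units = length(units),
                 interior = used_interior),
            class = "texture_spectrum")
}

# ---- Texture feature coding ------------------------------------------------

# Gradation class of an opposite neighbor pair:
#   0 both equal; 1 exactly one equal; 2 monotone (less/greater);
#   3 extremum (both less or both greater).
#' Texture feature coding (TFC)
#'
#' Each voxel is assigned a discrete code from the gradation classes of its 13
#' opposite neighbor pairs (both neighbors in-mask): class 0 when both sides
#' equal the center (within tolerance `a`), 1 when exactly one side is equal,
#' 2 when uptake passes monotonically through the voxel, 3 when the voxel is a
#' local extremum along the pair. The code is 13 times the mean class over
#' valid pairs, rounded — an integer in 0..39, equal to the class sum when all
#' 13 pairs are valid.
#'
#' @param q a `quantized_roi`.
#' @param a gradation tolerance in gray levels (default 0).
#' @return Object of class `tfc_volume`: `code` (3D integer array, NA where
#'   uncoded), `coded_idx`, `n_coded`.
#' @export
compute_tfc <- function(q, a = 0L) {
  stopifnot(inherits(q, "quantized_roi"))
  nbr <- neighbor_matrix(q$levels, q$mask_idx)
  lev <- q$levels[q$mask_idx]
  opp <- opposite_permutation()
  offs_idx <- which(vapply(seq_len(26L), function(k) k < opp[k], logical(1)))
  cls_sum <- numeric(length(lev))
  cls_n <- integer(length(lev))
  for (k in offs_idx) {
    g1 <- sign_tol(nbr[, k] - lev, a)
    g2 <- sign_tol(nbr[, opp[k]] - lev, a)
    ok <- !is.na(g1) & !is.na(g2)
    cls <- integer(sum(ok))
    a1 <- g1[ok]; a2 <- g2[ok]
    both_eq <- a1 == 0L & a2 == 0L
    one_eq <- xor(a1 == 0L, a2 == 0L)
    mono <- a1 != 0L & a2 != 0L & a1 != a2
    extr <- a1 != 0L & a2 != 0L & a1 == a2
    cls[one_eq] <- 1L; cls[mono] <- 2L; cls[extr] <- 3L
    cls_sum[ok] <- cls_sum[ok] + cls
    cls_n[ok] <- cls_n[ok] + 1L
  }
  coded <- cls_n > 0L
  if (!any(coded)) stopf("no voxel has a complete in-mask neighbor pair")
  code_val <- as.integer(round(13 * cls_sum[coded] / cls_n[coded]))
  arr <- array(NA_integer_, dim = dim(q$levels))
  arr[q$mask_idx[coded]] <- code_val
  structure(list(code = arr, coded_idx = q$mask_idx[coded],
                 n_coded = sum(coded)),
            class = "tfc_volume")
}

sign_tol <- function(x, a) {
  out <- sign(x)
  out[abs(x) <= a] <- 0L
  out
}

#' Texture feature coding co-occurrence matrix (TFCCM)
#'
#' Symmetric co-occurrence of TFC codes between 26-neighboring coded voxels,
#' normalized to probabilities.
#'
#' @param tfc a `tfc_volume` from [compute_tfc].
#' @return Object of class `tfccm`: `p` (40 x 40 probabilities over codes
#'   0..39), `n_pairs`.
#' @export
compute_tfccm <- function(tfc) {
  stopifnot(inherits(tfc, "tfc_volume"))
  lev <- tfc$code + 1L  # 1-based for tabulation
  cnt <- cooccurrence_counts(lev, 40L, 1L)
  total <- sum(cnt)
  if (total == 0) stopf("no adjacent coded voxel pairs")
  structure(list(p = cnt / total, n_pairs = total), class = "tfccm")
}
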