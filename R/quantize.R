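#' Fixed-bin-width SUV discretization
#'
#' Resamples the SUVs of the masked voxels to integer gray levels with a
#' constant intensity resolution: `level = floor((SUV - range_min)/bin_width) + 1`,
#' clipped to `[1, n_levels]`. With the defaults (bin width 0.4 SUV over the
#' window 0-25, 64 levels) every tumor is discretized on the same absolute
#' SUV scale; uptake above the window is absorbed by the top level.
#'
#' @param volume a [suv_volume].
#' @param mask a [roi_mask] congruent with `volume`.
#' @param bin_width SUV per gray level (default 0.4).
#' @param range_min,range_max SUV window of the resampling (defaults 0 and 25).
#' @param n_levels number of gray levels Ng (default 64).
#' @return Object of class `quantized_roi`: `levels` (integer array, NA
#'   outside the mask), `mask_idx` (linear indices of masked voxels), `Ng`,
#'   `bin_width`, `range_min`, `range_max`, `spacing`, `n_clipped` (number of
#'   masked voxels above the window).
#' @examples
#' v <- suv_volume(array(c(0, 0.39, 0.4, 30), c(1, 1, 4)))
#' m <- roi_mask(array(TRUE, c(1, 1, 4)))
#' quantize_fixed_bin_width(v, m)$levels
#' @export
quantize_fixed_bin_width <- function(volume, mask, bin_width = 0.4,
                                     range_min = 0, range_max = 25,
                                     n_levels = 64L) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$values), dim(mask$flags)))
    stopf("volume and mask dimensions differ")
  if (bin_width <= 0) stopf("`bin_width` must be > 0")
  if (range_max <= range_min) stopf("`range_max` must exceed `range_min`")
  idx <- which(mask$flags)
  if (length(idx) == 0L) stopf("empty mask: nothing to quantize")
  suv <- volume$values[idx]
  if (any(suv < range_min)) {
    bad <- arrayInd(idx[which(suv < range_min)[1]], dim(volume$values))
    stopf("masked voxel (%d, %d, %d) has SUV below range_min %.3g",
          bad[1], bad[2], bad[3], range_min)
  }
  lev <- floor((suv - range_min) / bin_width) + 1
  n_clipped <- sum(lev > n_levels)
  lev <- pmin(pmax(as.integer(lev), 1L), as.integer(n_levels))
  arr <- array(NA_integer_, dim = dim(volume$values))
  arr[idx] <- lev
  structure(list(levels = arr, mask_idx = idx, Ng = as.integer(n_levels),
                 bin_width = bin_width, range_min = range_min,
                 range_max = range_max, spacing = volume$spacing,
                 n_clipped = n_clipped),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("Quantized ROI: %d voxels, Ng = %d (bin width %.3g SUV, window %.3g-%.3g)\n",
              length(x$mask_idx), x$Ng, x$bin_width, x$range_min, x$range_max))
  if (x$n_clipped > 0)
    cat(sprintf("  note: %d voxel(s) above the window clipped to level %d\n",
                x$n_clipped, x$Ng))
  invisible(x)
}

#' Build a quantized ROI from explicit gray levels
#'
#' Constructor used for hand-built lattices (worked examples, oracle
#' comparisons): `NA` marks out-of-mask voxels.
#'
#' @param levels 3D integer array of gray levels, `NA` outside the mask.
#' @param Ng number of gray levels (defaults to the maximum present).
#' @param spacing voxel spacing (mm).
#' @return A `quantized_roi`.
#' @export
quantized_from_levels <- function(levels, Ng = max(levels, na.rm = TRUE),
                                  spacing = c(1, 1, 1)) {
  stopifnot(is.array(levels), length(dim(levels)) == 3L)
  structure(list(levels = levels, mask_idx = which(!is.na(levels)),
                 Ng = as.integer(Ng), bin_width = NA_real_,
                 range_min = NA_real_, range_max = NA_real_,
                 spacing = spacing, n_clipped = 0L),
            class = "quantized_roi")
}
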