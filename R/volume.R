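#' SUV volume container
#'
#' A minimal geometric data model for PET volumes already calibrated to
#' standardized uptake values (SUV): a 3D array of non-negative scalars, the
#' voxel spacing in millimetres and a world-space origin. All texture
#' computation downstream is lattice-based; spacing enters only through
#' metabolic tumor volume (MTV) and total lesion glycolysis (TLG).
#'
#' @param values 3D numeric array of SUVs (finite, non-negative).
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly positive).
#' @param origin numeric length-3, world coordinates of the first voxel (mm).
#' @return An object of class `suv_volume`.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 4)), spacing = c(3.91, 3.91, 3.27))
#' dim(v$values)
#' @export
suv_volume <- function(values, spacing = c(3.91, 3.91, 3.27), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3D array, got %s dimensions",
          if (is.array(values)) length(dim(values)) else "no")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1]
    stopf("non-finite SUV at linear voxel index %d", bad)
  }
  if (any(values < 0)) {
    bad <- which(values < 0)[1]
    stopf("negative SUV at linear voxel index %d", bad)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be three strictly positive lengths (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be three finite coordinates (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param flags 3D logical (or 0/1) array congruent with its volume.
#' @return Object of class `roi_mask` holding a logical array.
#' @export
roi_mask <- function(flags) {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    stopf("mask must be a 3D array")
  storage.mode(flags) <- "logical"
  if (anyNA(flags)) stopf("mask contains NA")
  structure(list(flags = flags), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %s voxels set of %s\n",
              sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Read an SUV volume from a NIfTI file
#'
#' Rejects non-3D data and volumes containing NaN or negative voxels; voxel
#' spacing is taken from the NIfTI pixdim and the origin from the affine
#' translation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [suv_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable volume '%s': %s", path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stopf("non-3D data in '%s' (%d dimensions)", path, length(dim(arr)))
  arr <- array(as.numeric(arr), dim = dim(arr))  # plain array, no NIfTI attributes
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("missing or invalid voxel spacing in '%s'", path)
  orig <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]), error = function(e) c(0, 0, 0))
  if (anyNA(arr) || any(!is.finite(arr))) {
    bad <- arrayInd(which(!is.finite(arr))[1], dim(arr))
    stopf("non-finite voxel at index (%d, %d, %d) in '%s'",
          bad[1], bad[2], bad[3], path)
  }
  if (any(arr < 0)) {
    bad <- arrayInd(which(arr < 0)[1], dim(arr))
    stopf("negative SUV at index (%d, %d, %d) in '%s'", bad[1], bad[2], bad[3], path)
  }
  suv_volume(arr, spacing = spacing, origin = orig)
}

#' Write an SUV volume (or mask) to NIfTI
#'
#' @param volume a [suv_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @param mask a [roi_mask]; written as a 0/1 integer volume.
#' @param spacing voxel spacing for the mask file (mm).
#' @export
write_mask <- function(mask, path, spacing = c(3.91, 3.91, 3.27)) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- array(as.integer(mask$flags), dim = dim(mask$flags))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path path to a mask file containing only 0/1 values.
#' @return A [roi_mask].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stopf("non-3D mask in '%s'", path)
  if (!all(arr %in% c(0, 1))) stopf("mask '%s' is not binary 0/1", path)
  roi_mask(array(arr == 1, dim = dim(arr)))
}
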