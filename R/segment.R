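# Connected components of a set of voxels under 26-connectivity.
# Returns an integer vector of component labels parallel to `idx`
# (linear voxel indices), labelled in decreasing size order with ties broken
# by smallest member index.
components26 <- function(idx, dims, values = NULL) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  edges <- vector("list", 13L)
  offs <- offsets13()
  for (k in seq_len(13L)) {
    pr <- offset_pairs(dims, offs[k, ])
    sel <- pos[pr$a] > 0L & pos[pr$b] > 0L
    if (!is.null(values)) sel <- sel & values[pr$a] == values[pr$b]
    edges[[k]] <- cbind(pos[pr$a[sel]], pos[pr$b[sel]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(em) > 0L) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership
  # relabel: 1 = largest component; ties -> smallest first voxel index
  sizes <- tabulate(comp)
  first_idx <- vapply(seq_along(sizes), function(cc) min(idx[comp == cc]), numeric(1))
  ord <- order(-sizes, first_idx)
  match(comp, ord)
}

#' Delineate the primary tumor by a fixed SUV threshold
#'
#' The mask is the 26-connected component of the voxel set `{SUV >= cutoff}`
#' containing `seed_point` if one is given, otherwise the largest such
#' component (single primary lesion assumed). The threshold is closed: a
#' voxel at exactly the cutoff is included.
#'
#' @param volume a [suv_volume].
#' @param cutoff SUV threshold (default 2.5).
#' @param seed_point optional integer length-3 voxel index inside the lesion,
#'   standing in for manual tumor localization.
#' @return Object of class `segmentation_result`: `mask` ([roi_mask]),
#'   `n_voxels`, `mtv_cm3`, `component_count`, `cutoff`.
#' @examples
#' p <- make_tumor_phantom(phantom_spec(c(10, 10, 10), base_suv = 8, seed = 1))
#' seg <- segment_fixed_threshold(p$volume)
#' seg$mtv_cm3
#' @export
segment_fixed_threshold <- function(volume, cutoff = 2.5, seed_point = NULL) {
  stopifnot(inherits(volume, "suv_volume"))
  if (cutoff <= 0) stopf("`cutoff` must be > 0")
  dims <- dim(volume$values)
  hot <- which(volume$values >= cutoff)
  if (length(hot) == 0L)
    stopf("undelineable tumor: no voxel reaches SUV >= %.3g", cutoff)
  comp <- components26(hot, dims)
  n_comp <- max(comp)
  if (!is.null(seed_point)) {
    seed_point <- as.integer(seed_point)
    if (length(seed_point) != 3L || any(seed_point < 1L) || any(seed_point > dims))
      stopf("`seed_point` must be a voxel index inside the grid")
    lin <- seed_point[1] + dims[1] * (seed_point[2] - 1L) +
      dims[1] * dims[2] * (seed_point[3] - 1L)
    hit <- match(lin, hot)
    if (is.na(hit))
      stopf("seed point (%d, %d, %d) is below the SUV cutoff %.3g",
            seed_point[1], seed_point[2], seed_point[3], cutoff)
    keep <- comp == comp[hit]
  } else {
    keep <- comp == 1L
  }
  flags <- array(FALSE, dim = dims)
  flags[hot[keep]] <- TRUE
  n_vox <- sum(keep)
  structure(list(mask = roi_mask(flags), n_voxels = n_vox,
                 mtv_cm3 = n_vox * prod(volume$spacing) / 1000,
                 component_count = n_comp, cutoff = cutoff),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Tumor segmentation (SUV >= %.3g): %d voxels, MTV %.2f cm3, %d component(s) found\n",
              x$cutoff, x$n_voxels, x$mtv_cm3, x$component_count))
  invisible(x)
}

#' Metabolic tumor volume of a segmentation
#'
#' MTV (cm3) is the masked voxel count times the voxel volume.
#'
#' @param result a `segmentation_result` (or [roi_mask]).
#' @param spacing voxel spacing (mm); required when `result` is a bare mask.
#' @return Volume in cm3.
#' @export
compute_mtv <- function(result, spacing = NULL) {
  if (inherits(result, "segmentation_result")) {
    n <- result$n_voxels
    if (is.null(spacing)) return(result$mtv_cm3)
  } else if (inherits(result, "roi_mask")) {
    n <- sum(result$flags)
  } else stopf("`result` must be a segmentation_result or roi_mask")
  if (n == 0L) stopf("empty mask has no metabolic volume")
  if (is.null(spacing)) stopf("`spacing` required for a bare mask")
  n * prod(as.numeric(spacing)) / 1000
}
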