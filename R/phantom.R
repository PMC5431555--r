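#' Specification of a synthetic tumor phantom
#'
#' Describes an ellipsoidal FDG-avid lesion embedded in cold parenchyma. Tumor
#' uptake is `base_suv` modulated by a log-normal random field: Gaussian white
#' noise smoothed with an isotropic Gaussian kernel of physical width
#' `correlation_length`, rescaled to standard deviation `heterogeneity_sd` on
#' the log scale and exponentiated, so intensities stay positive and the
#' coefficient of variation of tumor uptake is approximately
#' `heterogeneity_sd`. Background voxels carry `background_suv` plus small
#' Gaussian noise.
#'
#' @param semi_axes three ellipsoid semi-axes (mm), strictly positive.
#' @param base_suv median tumor SUV before modulation; must exceed `background_suv`.
#' @param heterogeneity_sd log-scale SD of the multiplicative intensity field
#'   (unitless); 0 gives a constant-uptake tumor.
#' @param correlation_length smoothing scale of the intensity field (mm).
#' @param background_suv parenchymal SUV level (>= 0).
#' @param background_noise_sd SD of additive background noise (SUV).
#' @param voxel_spacing three voxel edge lengths (mm).
#' @param grid_shape three positive integers, or `NULL` to auto-size the grid
#'   to the ellipsoid plus a margin.
#' @param margin_voxels margin around the ellipsoid when auto-sizing.
#' @param seed integer seed; all randomness in [make_tumor_phantom] flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes, base_suv, heterogeneity_sd = 0,
                         correlation_length = 10, background_suv = 0.5,
                         background_noise_sd = 0.05,
                         voxel_spacing = c(3.91, 3.91, 3.27),
                         grid_shape = NULL, margin_voxels = 3L, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stopf("`semi_axes` must be three strictly positive lengths (mm)")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stopf("`voxel_spacing` must be three strictly positive lengths (mm)")
  if (background_suv < 0) stopf("`background_suv` must be >= 0")
  if (base_suv <= background_suv) stopf("`base_suv` must exceed `background_suv`")
  if (heterogeneity_sd < 0) stopf("`heterogeneity_sd` must be >= 0")
  if (correlation_length <= 0) stopf("`correlation_length` must be > 0")
  if (is.null(grid_shape)) {
    grid_shape <- as.integer(2 * ceiling(semi_axes / voxel_spacing) + 2L * margin_voxels + 1L)
  } else {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stopf("`grid_shape` must be three positive integers")
  }
  structure(list(semi_axes = semi_axes, base_suv = base_suv,
                 heterogeneity_sd = heterogeneity_sd,
                 correlation_length = correlation_length,
                 background_suv = background_suv,
                 background_noise_sd = background_noise_sd,
                 voxel_spacing = voxel_spacing, grid_shape = grid_shape,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
smooth_gaussian3d <- function(arr, sigma) {
  dims <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- dims[ax]
    # banded convolution matrix with edge renormalization
    K <- matrix(0, n, n)
    for (j in seq(-half, half)) {
      idx <- seq_len(n)
      tgt <- idx + j
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[j + half + 1]
    }
    K <- K / rowSums(K)
    m <- matrix(aperm(arr, c(ax, setdiff(1:3, ax))), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, dim = c(n, dims[setdiff(1:3, ax)])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Generate a synthetic SUV tumor phantom
#'
#' Deterministic for a fixed `spec$seed`: two calls with the same spec return
#' bit-identical volumes. The returned mask marks the true ellipsoid extent
#' (voxel centers inside the ellipsoid), independent of any later threshold
#' segmentation.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` ([suv_volume]) and `mask` ([roi_mask]).
#' @examples
#' p <- make_tumor_phantom(phantom_spec(c(12, 12, 12), base_suv = 8, seed = 7))
#' sum(p$mask$flags)
#' @export
make_tumor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing
  extent_vox <- ceiling(spec$semi_axes / sp)
  if (any(2 * extent_vox + 4 > dims))
    stopf("ellipsoid (semi-axes %.1f/%.1f/%.1f mm) exceeds the %dx%dx%d grid; enlarge grid_shape",
          spec$semi_axes[1], spec$semi_axes[2], spec$semi_axes[3],
          dims[1], dims[2], dims[3])
  ctr <- (dims + 1) / 2
  xs <- (seq_len(dims[1]) - ctr[1]) * sp[1]
  ys <- (seq_len(dims[2]) - ctr[2]) * sp[2]
  zs <- (seq_len(dims[3]) - ctr[3]) * sp[3]
  d2 <- outer(outer((xs / spec$semi_axes[1])^2, (ys / spec$semi_axes[2])^2, `+`),
              (zs / spec$semi_axes[3])^2, `+`)
  inside <- d2 <= 1
  vals <- with_seed(spec$seed, {
    v <- array(abs(rnorm(prod(dims), mean = spec$background_suv,
                         sd = spec$background_noise_sd)), dim = dims)
    if (spec$heterogeneity_sd > 0) {
      field <- array(rnorm(prod(dims)), dim = dims)
      field <- smooth_gaussian3d(field, sigma = spec$correlation_length / sp)
      field <- field - mean(field[inside])
      s <- sd(field[inside])
      if (s > 0) field <- field / s
      v[inside] <- spec$base_suv * exp(spec$heterogeneity_sd * field[inside])
    } else {
      v[inside] <- spec$base_suv
    }
    v
  })
  list(volume = suv_volume(vals, spacing = sp),
       mask = roi_mask(inside))
}

#' Default tumor archetypes
#'
#' Three phantom templates calibrated to the published per-cluster medians of
#' a locally advanced breast cancer cohort: archetype I is large
#' (MTV about 63 cm3), hot and heterogeneous; archetype II mid-sized (about
#' 18 cm3), hot and heterogeneous; archetype III small (about 3 cm3), mild and
#' homogeneous. Semi-axes are sphere-equivalent radii of the target volumes;
#' `base_suv` is the target SUVmean deflated by the log-normal mean factor
#' exp(sd^2/2); `heterogeneity_sd` equals the target coefficient of variation.
#'
#' @return Named list of three [phantom_spec] templates ("I", "II", "III").
#' @export
default_archetypes <- function() {
  calib <- list(
    I   = list(mtv = 62.9, suv_mean = 4.9, cv = 0.42),
    II  = list(mtv = 18.4, suv_mean = 6.1, cv = 0.45),
    III = list(mtv = 2.9,  suv_mean = 3.6, cv = 0.21)
  )
  lapply(calib, function(a) {
    r <- (3 * a$mtv * 1000 / (4 * pi))^(1 / 3)
    phantom_spec(semi_axes = rep(r, 3),
                 base_suv = a$suv_mean / exp(a$cv^2 / 2),
                 heterogeneity_sd = a$cv,
                 correlation_length = 10)
  })
}

#' Outcome model for synthetic cohorts
#'
#' Cluster-conditional outcome generator: pathologic complete response (pCR)
#' is Bernoulli per archetype; recurrence times are exponential with the
#' per-archetype hazard, right-censored by a uniform follow-up draw. Default
#' pCR probabilities follow the published per-cluster rates (20.0%, 48.0%,
#' 5.4%); default hazards approximate the published recurrence pattern
#' (events concentrated in the large-tumor archetype).
#'
#' @param pcr_prob_per_cluster probabilities in `[0,1]`, one per archetype.
#' @param recurrence_hazard_per_cluster events per month, one per archetype (>= 0).
#' @param censor_time_range two positive months, uniform censoring window.
#' @param marker_probs list of per-archetype probabilities for the clinical
#'   markers er, pgr, her2, ki67_high and stage III.
#' @param seed integer seed.
#' @return Object of class `outcome_model`.
#' @export
outcome_model <- function(pcr_prob_per_cluster = c(0.200, 0.480, 0.054),
                          recurrence_hazard_per_cluster = c(0.010, 0.0005, 0.0008),
                          censor_time_range = c(24, 57),
                          marker_probs = list(
                            er = c(0.30, 0.32, 0.65),
                            pgr = c(0.20, 0.16, 0.49),
                            her2 = c(0.33, 0.21, 0.29),
                            ki67_high = c(0.80, 0.64, 0.32),
                            stage3 = c(0.60, 0.48, 0.40)),
                          seed = 1L) {
  if (any(pcr_prob_per_cluster < 0 | pcr_prob_per_cluster > 1))
    stopf("pCR probabilities must lie in [0,1]")
  if (any(recurrence_hazard_per_cluster < 0))
    stopf("recurrence hazards must be >= 0")
  if (length(censor_time_range) != 2L || any(censor_time_range <= 0) ||
      diff(censor_time_range) < 0)
    stopf("`censor_time_range` must be two positive increasing months")
  structure(list(pcr_prob = pcr_prob_per_cluster,
                 hazard = recurrence_hazard_per_cluster,
                 censor_range = as.numeric(censor_time_range),
                 marker_probs = marker_probs,
                 seed = as.integer(seed)),
            class = "outcome_model")
}

#' Simulate a synthetic patient cohort
#'
#' Each patient draws phantom parameters around its archetype template
#' (log-normal multiplicative jitter on semi-axes and base SUV), then a pCR
#' indicator and a censored recurrence time from the outcome model. True
#' archetype labels are retained so clustering can be scored against the
#' planted partition.
#'
#' @param n_per_archetype integer counts, one per archetype (all >= 1).
#' @param archetypes list of [phantom_spec] templates; default [default_archetypes].
#' @param outcomes an [outcome_model].
#' @param jitter_sd log-normal SD of per-patient jitter on semi-axes and base SUV.
#' @param seed master integer seed; per-patient seeds are derived from it.
#' @return List with `volumes` (list of [suv_volume]), `masks` (list of
#'   [roi_mask]) and `cohort` (data.frame: patient_id, archetype, er, pgr,
#'   her2, ki67_high, stage, pcr, dfs_months, event).
#' @export
make_cohort <- function(n_per_archetype = c(10L, 25L, 37L),
                        archetypes = default_archetypes(),
                        outcomes = outcome_model(),
                        jitter_sd = 0.15, seed = 20090701L) {
  if (length(archetypes) < 1L) stopf("empty archetype list")
  if (length(n_per_archetype) != length(archetypes))
    stopf("`n_per_archetype` must match the number of archetypes")
  if (any(n_per_archetype < 1L)) stopf("all archetype counts must be >= 1")
  k <- length(archetypes)
  arch_names <- names(archetypes)
  if (is.null(arch_names)) arch_names <- as.character(seq_len(k))
  n_total <- sum(n_per_archetype)
  arch_of <- rep(seq_len(k), times = n_per_archetype)

  volumes <- vector("list", n_total)
  masks <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    a <- arch_of[i]
    tmpl <- archetypes[[a]]
    si <- child_seed(seed, i)
    pars <- with_seed(child_seed(si, 1L), {
      list(axes = tmpl$semi_axes * exp(rnorm(3, sd = jitter_sd)),
           base = tmpl$base_suv * exp(rnorm(1, sd = jitter_sd)))
    })
    sp <- phantom_spec(semi_axes = pars$axes, base_suv = pars$base,
                       heterogeneity_sd = tmpl$heterogeneity_sd,
                       correlation_length = tmpl$correlation_length,
                       background_suv = tmpl$background_suv,
                       background_noise_sd = tmpl$background_noise_sd,
                       voxel_spacing = tmpl$voxel_spacing,
                       seed = child_seed(si, 2L))
    ph <- make_tumor_phantom(sp)
    volumes[[i]] <- ph$volume
    masks[[i]] <- ph$mask
    out <- with_seed(child_seed(si, 3L), {
      pcr <- rbinom(1, 1, outcomes$pcr_prob[a])
      cens <- runif(1, outcomes$censor_range[1], outcomes$censor_range[2])
      tt <- if (outcomes$hazard[a] > 0) rexp(1, rate = outcomes$hazard[a]) else Inf
      mp <- outcomes$marker_probs
      list(pcr = pcr,
           dfs = min(tt, cens),
           event = as.integer(tt <= cens),
           er = rbinom(1, 1, mp$er[a]), pgr = rbinom(1, 1, mp$pgr[a]),
           her2 = rbinom(1, 1, mp$her2[a]),
           ki67 = rbinom(1, 1, mp$ki67_high[a]),
           stage = if (rbinom(1, 1, mp$stage3[a]) == 1) "III" else "II")
    })
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i), archetype = arch_names[a],
      er = out$er, pgr = out$pgr, her2 = out$her2, ki67_high = out$ki67,
      stage = out$stage, pcr = out$pcr,
      dfs_months = out$dfs, event = out$event,
      stringsAsFactors = FALSE)
  }
  list(volumes = volumes, masks = masks, cohort = do.call(rbind, rows))
}

#' Write a cohort table as CSV
#' @param cohort the `cohort` data.frame from [make_cohort] (optionally with
#'   feature columns appended).
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
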