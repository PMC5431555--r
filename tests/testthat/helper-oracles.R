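# Naive brute-force enumerators over voxels/pairs/zones/runs/neighborhoods.
# Deliberately slow and independent of the package's vectorized code paths;
# used only on small lattices.

all_offsets <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
}

in_grid <- function(v, dims) all(v >= 1) && all(v <= dims)

lev_at <- function(levels, v) levels[v[1], v[2], v[3]]

# directed co-occurrence counts over all 26 offsets at `distance`
oracle_glcm_counts <- function(levels, Ng, distance = 1L) {
  dims <- dim(levels)
  offs <- all_offsets() * distance
  cnt <- matrix(0, Ng, Ng)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    li <- levels[ix, iy, iz]
    if (is.na(li)) next
    for (k in seq_len(nrow(offs))) {
      w <- c(ix, iy, iz) + offs[k, ]
      if (!in_grid(w, dims)) next
      lj <- lev_at(levels, w)
      if (is.na(lj)) next
      cnt[li, lj] <- cnt[li, lj] + 1
    }
  }
  cnt
}

# run-length counts aggregated over the 13 unique directions
oracle_glrlm_counts <- function(levels, Ng) {
  dims <- dim(levels)
  offs <- all_offsets()
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  runs <- list()
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
      v <- c(ix, iy, iz)
      li <- lev_at(levels, v)
      if (is.na(li)) next
      prev <- v - o
      if (in_grid(prev, dims) && !is.na(lev_at(levels, prev)) &&
          lev_at(levels, prev) == li) next  # not a run start
      len <- 1L
      w <- v + o
      while (in_grid(w, dims) && !is.na(lev_at(levels, w)) &&
             lev_at(levels, w) == li) {
        len <- len + 1L
        w <- w + o
      }
      runs[[length(runs) + 1L]] <- c(li, len)
    }
  }
  rm_ <- do.call(rbind, runs)
  rmax <- max(rm_[, 2])
  out <- matrix(0, Ng, rmax)
  for (r in seq_len(nrow(rm_))) out[rm_[r, 1], rm_[r, 2]] <- out[rm_[r, 1], rm_[r, 2]] + 1
  out
}

# zone counts: BFS flood fill per gray level, 26-connected
oracle_glszm_counts <- function(levels, Ng) {
  dims <- dim(levels)
  offs <- all_offsets()
  seen <- array(FALSE, dims)
  zones <- list()
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    if (seen[ix, iy, iz] || is.na(levels[ix, iy, iz])) next
    li <- levels[ix, iy, iz]
    queue <- list(c(ix, iy, iz))
    seen[ix, iy, iz] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (!in_grid(w, dims) || seen[w[1], w[2], w[3]]) next
        lw <- lev_at(levels, w)
        if (is.na(lw) || lw != li) next
        seen[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
    zones[[length(zones) + 1L]] <- c(li, size)
  }
  zm <- do.call(rbind, zones)
  out <- matrix(0, Ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) out[zm[r, 1], zm[r, 2]] <- out[zm[r, 1], zm[r, 2]] + 1
  out
}

# per-voxel 26-neighborhood values (NA when absent)
oracle_neighbors <- function(levels, v) {
  dims <- dim(levels)
  offs <- all_offsets()
  out <- rep(NA_real_, 26)
  for (k in seq_len(26)) {
    w <- v + offs[k, ]
    if (in_grid(w, dims)) out[k] <- lev_at(levels, w)
  }
  out
}

oracle_ngtdm <- function(levels, Ng) {
  dims <- dim(levels)
  n_i <- numeric(Ng); s_i <- numeric(Ng); nvalid <- 0L
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    li <- levels[ix, iy, iz]
    if (is.na(li)) next
    nb <- oracle_neighbors(levels, c(ix, iy, iz))
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    nvalid <- nvalid + 1L
    n_i[li] <- n_i[li] + 1
    s_i[li] <- s_i[li] + abs(li - mean(nb))
  }
  list(p_i = n_i / nvalid, s_i = s_i, n_i = n_i, n_valid = nvalid)
}

oracle_ngldm <- function(levels, Ng, a = 0) {
  dims <- dim(levels)
  d <- matrix(0, Ng, 27)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    li <- levels[ix, iy, iz]
    if (is.na(li)) next
    nb <- oracle_neighbors(levels, c(ix, iy, iz))
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    k <- sum(abs(nb - li) <= a)
    d[li, k + 1] <- d[li, k + 1] + 1
  }
  d
}

# ternary texture-unit strings; interior rule mirrors the package contract
oracle_texture_units <- function(levels) {
  dims <- dim(levels)
  units <- character(0)
  codes_all <- list()
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    li <- levels[ix, iy, iz]
    if (is.na(li)) next
    nb <- oracle_neighbors(levels, c(ix, iy, iz))
    codes_all[[length(codes_all) + 1L]] <- 1L + sign(nb - li)
  }
  cm <- do.call(rbind, codes_all)
  valid <- rowSums(!is.na(cm))
  interior <- valid == 26
  if (any(interior)) cm <- cm[interior, , drop = FALSE]
  else {
    cm <- cm[valid > 0, , drop = FALSE]
    cm[is.na(cm)] <- 1L
  }
  apply(cm, 1, paste0, collapse = "")
}

# TFC codes per voxel from the 13 opposite neighbor pairs
oracle_tfc_codes <- function(levels, a = 0) {
  dims <- dim(levels)
  offs <- all_offsets()
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  out <- array(NA_integer_, dims)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    li <- levels[ix, iy, iz]
    if (is.na(li)) next
    cls <- integer(0)
    for (k in seq_len(nrow(offs))) {
      w1 <- c(ix, iy, iz) + offs[k, ]; w2 <- c(ix, iy, iz) - offs[k, ]
      if (!in_grid(w1, dims) || !in_grid(w2, dims)) next
      l1 <- lev_at(levels, w1); l2 <- lev_at(levels, w2)
      if (is.na(l1) || is.na(l2)) next
      g1 <- if (abs(l1 - li) <= a) 0L else sign(l1 - li)
      g2 <- if (abs(l2 - li) <= a) 0L else sign(l2 - li)
      cls <- c(cls,
               if (g1 == 0 && g2 == 0) 0L
               else if (xor(g1 == 0, g2 == 0)) 1L
               else if (g1 != g2) 2L
               else 3L)
    }
    if (length(cls)) out[ix, iy, iz] <- as.integer(round(13 * mean(cls)))
  }
  out
}

# random small quantized ROI guaranteed to have adjacent in-mask pairs
random_small_roi <- function(seed, max_dim = 6L, n_levels = 4L) {
  set.seed(seed)
  repeat {
    dims <- sample(3:max_dim, 3, replace = TRUE)
    mask <- array(runif(prod(dims)) < 0.7, dims)
    if (sum(mask) < 4) next
    lev <- array(NA_integer_, dims)
    lev[mask] <- sample.int(n_levels, sum(mask), replace = TRUE)
    q <- quantized_from_levels(lev, Ng = n_levels)
    # need at least one adjacent in-mask pair and one complete opposite pair
    ok <- tryCatch({
      compute_glcm(q)
      compute_tfccm(compute_tfc(q))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(q)
  }
}

# expand a texture spectrum back into its multiset of unit strings
unit_strings_of <- function(ts) {
  rep(names(ts$spectrum), as.integer(ts$spectrum))
}
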