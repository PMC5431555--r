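#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying inside 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + as.double(index) * 12347L) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# All 26 lattice offsets of the 3D Moore neighborhood, one per row.
offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
}

# The 13 unique (half-space) directions; their negations complete the 26.
offsets13 <- function() {
  o <- offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
  o[keep, , drop = FALSE]
}

# Linear indices of all voxel pairs (a, b) with b = a + offset, both inside dims.
offset_pairs <- function(dims, offset) {
  lo <- pmax(1L, 1L - offset)
  hi <- pmin(dims, dims - offset)
  if (any(lo > hi)) return(list(a = integer(0), b = integer(0)))
  rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
  lin <- array(seq_len(prod(dims)), dim = dims)
  list(a = as.integer(lin[rx, ry, rz]),
       b = as.integer(lin[rx + offset[1], ry + offset[2], rz + offset[3]]))
}

# nvox x 26 matrix of neighbor values for the masked voxels of a labelled array;
# NA where the neighbor falls outside the grid or outside the mask.
neighbor_matrix <- function(values, mask_idx) {
  dims <- dim(values)
  n <- length(mask_idx)
  pos <- integer(prod(dims))
  pos[mask_idx] <- seq_len(n)
  offs <- offsets26()
  out <- matrix(NA_real_, nrow = n, ncol = 26L)
  for (k in seq_len(26L)) {
    pr <- offset_pairs(dims, offs[k, ])
    sel <- pos[pr$a] > 0L & pos[pr$b] > 0L
    out[pos[pr$a[sel]], k] <- values[pr$b[sel]]
  }
  out
}

shannon_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p, base = base))
}
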