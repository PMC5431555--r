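# Shared small fixtures, built in code.

# 1x1x4 rod with levels 1,1,2,2 — the hand-enumerated worked example
rod_1124 <- function() {
  quantized_from_levels(array(c(1L, 1L, 2L, 2L), c(1, 1, 4)), Ng = 2L)
}

constant_roi <- function(n = 27L, level = 3L, Ng = 8L) {
  side <- ceiling(n^(1 / 3))
  lev <- array(NA_integer_, c(side, side, side))
  lev[seq_len(n)] <- level
  quantized_from_levels(lev, Ng = Ng)
}

# small heterogeneous phantom used across texture tests
small_hot_phantom <- function(seed = 11L, het = 0.3) {
  make_tumor_phantom(phantom_spec(c(12, 12, 12), base_suv = 6,
                                  heterogeneity_sd = het, seed = seed))
}

# three well-separated Gaussian blobs in feature space
blob_matrix <- function(n = c(10, 12, 14), dim_f = 5L, sep = 12, seed = 42L) {
  set.seed(seed)
  centers <- diag(sep, 3, dim_f)
  x <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(n[g] * dim_f), n[g], dim_f) +
      matrix(centers[g, ], n[g], dim_f, byrow = TRUE)))
  list(x = x, truth = rep(1:3, times = n))
}
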