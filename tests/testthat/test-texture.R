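# Hand-enumerated worked examples ------------------------------------------

test_that("GLCM of the 1x1x4 rod matches the hand enumeration", {
  g <- compute_glcm(rod_1124())
  expect_equal(g$p[1, 1], 1 / 3)
  expect_equal(g$p[1, 2], 1 / 6)
  expect_equal(g$p[2, 1], 1 / 6)
  expect_equal(g$p[2, 2], 1 / 3)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  f <- glcm_features(g)
  # closed forms on the 4-entry matrix: H = (2/3)log2(3) + (1/3)log2(6)
  expect_equal(unname(f["NL_Entropy^GLCM"]), (2 / 3) * log2(3) + (1 / 3) * log2(6),
               tolerance = 1e-12)
  expect_equal(unname(f["NL_Homogeneity^GLCM"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(f["NL_Dissimilarity^GLCM"]), 1 / 3, tolerance = 1e-12)
})

test_that("GLSZM of the 1x1x4 rod: two zones of size two, ZP 0.5, HILZE 10", {
  z <- compute_glszm(rod_1124())
  expect_equal(z$n_zones, 2L)
  expect_equal(z$z[1, 2], 1)
  expect_equal(z$z[2, 2], 1)
  f <- glszm_features(z)
  expect_equal(unname(f["ZP^GLSZM"]), 0.5)
  expect_equal(unname(f["HILZE^GLSZM"]), (1 * 1 * 4 + 1 * 4 * 4) / 2)
})

test_that("GLRLM of the 1x1x4 rod counts the axial runs correctly", {
  r <- compute_glrlm(rod_1124())
  # z-direction: two runs of length 2; the other 12 directions: 4 singletons each
  expect_equal(r$r[1, 2], 1)
  expect_equal(r$r[2, 2], 1)
  expect_equal(sum(r$r[, 1]), 48)          # 12 directions x 4 voxels
  expect_equal(sum(col(r$r) * r$r), 4 * 13)  # every direction covers each voxel once
  f <- glrlm_features(r)
  expect_equal(unname(f["RP^GLRLM"]), sum(r$r) / (4 * 13))
})

test_that("NGLDM of the 1x1x4 rod gives one dependent neighbor per voxel", {
  d <- compute_ngldm(rod_1124(), a = 0)
  # all four voxels have dependence count 1
  expect_equal(sum(d$d[, 2]), 4)
  expect_equal(sum(d$d), 4)
})

test_that("NGLDM saturates when the tolerance spans all levels", {
  q <- random_small_roi(301)
  full <- compute_ngldm(q, a = q$Ng)
  nbr_counts <- rowSums(!is.na(petradiomics:::neighbor_matrix(q$levels, q$mask_idx)))
  expect_equal(sum(full$d), sum(nbr_counts > 0))
  # every valid neighbor is dependent: dependence = neighbor count
  f0 <- ngldm_features(compute_ngldm(q, a = 0))
  ffull <- ngldm_features(full)
  expect_gte(unname(ffull["LNE^NGLDM"]), unname(f0["LNE^NGLDM"]))
})

test_that("a 3x3x3 constant block gives its center voxel 26 dependents", {
  q <- quantized_from_levels(array(2L, c(3, 3, 3)), Ng = 4L)
  d <- compute_ngldm(q, a = 0)
  expect_equal(d$d[2, 27], 1)   # one voxel (the center) with k = 26
})

test_that("NGTDM contrast of a hand 2x2x1 grid matches the closed form", {
  lev <- array(c(1L, 3L, 2L, 4L), c(2, 2, 1))
  q <- quantized_from_levels(lev, Ng = 4L)
  m <- compute_ngtdm(q)
  o <- oracle_ngtdm(lev, 4L)
  expect_equal(m$p_i, o$p_i)
  expect_equal(m$s_i, o$s_i)
  f <- ngtdm_features(m)
  # independent closed form for contrast on the oracle quantities
  occ <- which(o$n_i > 0); Ngp <- length(occ)
  contrast <- sum(outer(o$p_i[occ], o$p_i[occ]) *
                  outer(occ, occ, function(a, b) (a - b)^2)) /
    (Ngp * (Ngp - 1)) * sum(o$s_i) / o$n_valid
  expect_equal(unname(f["Contrast^NGTDM"]), contrast)
})

# Degenerate limits ----------------------------------------------------------

test_that("constant ROI hits every degenerate limit", {
  n <- 27L
  q <- constant_roi(n = n)
  g <- glcm_features(compute_glcm(q))
  expect_equal(unname(g["NL_Entropy^GLCM"]), 0)
  expect_equal(unname(g["NL_Homogeneity^GLCM"]), 1)
  expect_equal(unname(g["NL_Dissimilarity^GLCM"]), 0)
  z <- glszm_features(compute_glszm(q))
  expect_equal(unname(z["ZP^GLSZM"]), 1 / n)
  t_ <- ngtdm_features(compute_ngtdm(q))
  expect_equal(unname(t_["Contrast^NGTDM"]), 0)
  ts <- compute_texture_spectrum(q)
  expect_equal(length(ts$spectrum), 1L)       # single all-equal texture unit
  tfc <- compute_tfc(q)
  expect_true(all(tfc$code[tfc$coded_idx] == 0L))
  expect_equal(unname(tfccm_features(compute_tfccm(tfc))["Entropy^TFCCM"]), 0)
  v <- suv_volume(array(4, c(3, 3, 3)))
  s <- suv_statistics(v, roi_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(unname(s["CV"]), 0)
  expect_equal(unname(s["Skewness"]), 0)
})

test_that("a strictly increasing 1D ramp collapses TFC to a single monotone class", {
  lev <- array(1:6, c(1, 1, 6))
  q <- quantized_from_levels(lev, Ng = 6L)
  tfc <- compute_tfc(q)
  codes <- tfc$code[tfc$coded_idx]
  expect_equal(length(unique(codes)), 1L)
  expect_equal(unique(codes), 26L)   # 13 * mean class 2 (monotone)
})

# SUV statistics -------------------------------------------------------------

test_that("population statistics of {2,4,6} match the closed form", {
  v <- suv_volume(array(c(2, 4, 6), c(1, 1, 3)), spacing = c(10, 10, 10))
  m <- roi_mask(array(TRUE, c(1, 1, 3)))
  s <- suv_statistics(v, m)
  expect_equal(unname(s["SUV_mean"]), 4)
  expect_equal(unname(s["SUV_sd"]), sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(unname(s["CV"]), sqrt(8 / 3) / 4, tolerance = 1e-12)
  expect_equal(unname(s["MTV"]), 3)
  expect_equal(unname(s["TLG"]), 12)
})

test_that("TLG = SUVmean x MTV and MTV = count x voxel volume on every extraction", {
  for (s in 1:3) {
    p <- small_hot_phantom(seed = s)
    seg <- segment_fixed_threshold(p$volume)
    fv <- extract_all_features(p$volume, seg$mask)
    expect_equal(unname(fv["TLG"]), unname(fv["SUV_mean"] * fv["MTV"]),
                 tolerance = 1e-9)
    expect_equal(unname(fv["MTV"]),
                 seg$n_voxels * prod(p$volume$spacing) / 1000,
                 tolerance = 1e-9)
  }
})

# Registry and full extraction -----------------------------------------------

test_that("the registry holds exactly 109 uniquely named features incl. the clinical ones", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 109L)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_true(all(c("SUV_max", "SUV_mean", "MTV", "TLG", "CV", "Skewness",
                    "NL_Entropy^GLCM", "NL_Homogeneity^GLCM",
                    "NL_Dissimilarity^GLCM", "ZP^GLSZM", "HILZE^GLSZM")
                  %in% reg$name))
})

test_that("extraction emits the registry exactly, finite, in order", {
  p <- small_hot_phantom()
  seg <- segment_fixed_threshold(p$volume)
  fv <- extract_all_features(p$volume, seg$mask)
  expect_identical(names(fv), feature_registry()$name)
  expect_true(all(is.finite(fv)))
})

test_that("features are invariant under axis permutation of an isotropic ROI", {
  set.seed(77)
  lev <- array(sample.int(4, 5^3, replace = TRUE), c(5, 5, 5))
  vals <- (lev - 1) * 0.4 + 3  # SUVs landing mid-bin
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    v1 <- suv_volume(vals, spacing = c(1, 1, 1))
    v2 <- suv_volume(aperm(vals, perm), spacing = c(1, 1, 1))
    m1 <- roi_mask(array(TRUE, c(5, 5, 5)))
    f1 <- extract_all_features(v1, m1)
    f2 <- extract_all_features(v2, m1)
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("mean GLCM entropy increases with the planted heterogeneity", {
  mean_ent <- function(het) {
    mean(vapply(1:20, function(s) {
      p <- make_tumor_phantom(phantom_spec(c(12, 12, 12), base_suv = 6,
                                           heterogeneity_sd = het, seed = 100 + s))
      seg <- segment_fixed_threshold(p$volume)
      q <- quantize_fixed_bin_width(p$volume, seg$mask)
      unname(glcm_features(compute_glcm(q))["NL_Entropy^GLCM"])
    }, numeric(1)))
  }
  e1 <- mean_ent(0.05); e2 <- mean_ent(0.2); e3 <- mean_ent(0.45)
  expect_lt(e1, e2)
  expect_lt(e2, e3)
})

test_that("archetype phantoms show the published entropy ordering and plausible ranges", {
  arch <- default_archetypes()
  ent <- vapply(names(arch), function(nm) {
    mean(vapply(1:5, function(s) {
      tmpl <- arch[[nm]]
      sp <- phantom_spec(tmpl$semi_axes, tmpl$base_suv,
                         heterogeneity_sd = tmpl$heterogeneity_sd,
                         correlation_length = tmpl$correlation_length,
                         seed = 200 + s)
      p <- make_tumor_phantom(sp)
      seg <- segment_fixed_threshold(p$volume)
      q <- quantize_fixed_bin_width(p$volume, seg$mask)
      unname(glcm_features(compute_glcm(q))["NL_Entropy^GLCM"])
    }, numeric(1)))
  }, numeric(1))
  # published medians order III < I < II
  expect_lt(ent["III"], ent["I"])
  expect_lt(ent["I"], ent["II"])
  # large and small archetypes land inside the published 2.5-7.0 span
  expect_gt(ent["III"], 2.5); expect_lt(ent["III"], 7.0)
  expect_gt(ent["I"], 2.5); expect_lt(ent["I"], 7.0)
})

# Brute-force oracle equivalence (small) --------------------------------------

test_that("vectorized matrices equal the brute-force enumerators on random small ROIs", {
  for (s in 1:8) {
    q <- random_small_roi(s)
    lev <- q$levels; Ng <- q$Ng
    g <- compute_glcm(q)
    oc <- oracle_glcm_counts(lev, Ng)
    expect_equal(g$p * g$n_pairs, oc, tolerance = 1e-9)
    r <- compute_glrlm(q)
    or_ <- oracle_glrlm_counts(lev, Ng)
    expect_equal(r$r[, seq_len(ncol(or_)), drop = FALSE], or_)
    z <- compute_glszm(q)
    oz <- oracle_glszm_counts(lev, Ng)
    expect_equal(z$z[, seq_len(ncol(oz)), drop = FALSE], oz)
    nt <- compute_ngtdm(q)
    ot <- oracle_ngtdm(lev, Ng)
    expect_equal(nt$p_i, ot$p_i, tolerance = 1e-12)
    expect_equal(nt$s_i, ot$s_i, tolerance = 1e-12)
    nd <- compute_ngldm(q, a = 0)
    expect_equal(nd$d, oracle_ngldm(lev, Ng, 0))
    ts <- compute_texture_spectrum(q)
    expect_equal(sort(unit_strings_of(ts)), sort(oracle_texture_units(lev)))
    tf <- compute_tfc(q)
    expect_equal(tf$code, oracle_tfc_codes(lev))
    tm <- compute_tfccm(tf)
    expect_equal(tm$p * tm$n_pairs, oracle_glcm_counts(tf$code + 1L, 40L),
                 tolerance = 1e-9)
  }
})
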