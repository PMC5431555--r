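# Declarative registry of the 109 texture features: the single source of
# truth for feature names, family allocation and extraction order. Validated
# at load; extract_all_features() refuses to return anything that does not
# match it exactly.

registry_families <- function() {
  list(
    Stats = c("SUV_max", "SUV_min", "SUV_mean", "SUV_median", "SUV_sd",
              "SUV_var", "SUV_range", "SUV_q1", "SUV_q3", "SUV_iqr",
              "SUV_rms", "CV", "Skewness", "Kurtosis", "HistEntropy",
              "HistUniformity", "MTV", "TLG"),
    GLCM = c("Energy^GLCM", "NL_Entropy^GLCM", "NL_Dissimilarity^GLCM",
             "Contrast^GLCM", "NL_Homogeneity^GLCM", "IDM^GLCM",
             "InverseVariance^GLCM", "Correlation^GLCM",
             "Autocorrelation^GLCM", "ClusterTendency^GLCM",
             "ClusterShade^GLCM", "ClusterProminence^GLCM",
             "MaxProbability^GLCM", "Variance^GLCM", "SumMean^GLCM",
             "SumVariance^GLCM", "SumEntropy^GLCM", "DiffMean^GLCM",
             "DiffVariance^GLCM", "DiffEntropy^GLCM", "IMC1^GLCM",
             "IMC2^GLCM"),
    GLRLM = c("SRE^GLRLM", "LRE^GLRLM", "GLN^GLRLM", "RLN^GLRLM", "RP^GLRLM",
              "LGRE^GLRLM", "HGRE^GLRLM", "SRLGE^GLRLM", "SRHGE^GLRLM",
              "LRLGE^GLRLM", "LRHGE^GLRLM"),
    GLSZM = c("SZE^GLSZM", "LZE^GLSZM", "GLN^GLSZM", "ZSN^GLSZM", "ZP^GLSZM",
              "LIZE^GLSZM", "HIZE^GLSZM", "LISZE^GLSZM", "HISZE^GLSZM",
              "LILZE^GLSZM", "HILZE^GLSZM"),
    NGTDM = c("Coarseness^NGTDM", "Contrast^NGTDM", "Busyness^NGTDM",
              "Complexity^NGTDM", "Strength^NGTDM"),
    NGLDM = c("SNE^NGLDM", "LNE^NGLDM", "GLN^NGLDM", "NN^NGLDM",
              "SecondMoment^NGLDM", "Entropy^NGLDM"),
    TS = c("BWS^TS", "GS^TS", "DD^TS", "CS^TS", "MicroStructure^TS",
           "Anisotropy^TS", "EqualFraction^TS", "Entropy^TS"),
    TFC = c("MeanCode^TFC", "Variance^TFC", "MeanConvergence^TFC",
            "CodeEntropy^TFC", "CodeEnergy^TFC", "Homogeneity^TFC",
            "Coarseness^TFC", "MaxCodeFraction^TFC"),
    TFCCM = c("Energy^TFCCM", "Entropy^TFCCM", "Dissimilarity^TFCCM",
              "Contrast^TFCCM", "Homogeneity^TFCCM", "IDM^TFCCM",
              "Correlation^TFCCM", "ClusterTendency^TFCCM",
              "ClusterShade^TFCCM", "ClusterProminence^TFCCM",
              "MaxProbability^TFCCM", "Variance^TFCCM", "SumMean^TFCCM",
              "SumVariance^TFCCM", "SumEntropy^TFCCM", "DiffMean^TFCCM",
              "DiffVariance^TFCCM", "DiffEntropy^TFCCM", "IMC1^TFCCM",
              "IMC2^TFCCM")
  )
}

#' The 109-feature registry
#'
#' Names and family allocation of every texture feature the extractor emits,
#' in extraction order. Matrix-family features carry the matrix name after a
#' caret (`NL_Entropy^GLCM`); SUV histogram statistics keep their plain
#' names. The registry is validated on construction: exactly 109 unique
#' names, including the eleven features called out individually in the
#' clinical analysis (SUV_max, SUV_mean, MTV, TLG, CV, Skewness,
#' NL_Entropy^GLCM, NL_Homogeneity^GLCM, NL_Dissimilarity^GLCM, ZP^GLSZM,
#' HILZE^GLSZM).
#'
#' @return data.frame with columns `name` and `family`.
#' @examples
#' nrow(feature_registry())
#' @export
feature_registry <- function() {
  fams <- registry_families()
  reg <- data.frame(
    name = unlist(fams, use.names = FALSE),
    family = rep(names(fams), lengths(fams)),
    stringsAsFactors = FALSE)
  if (nrow(reg) != 109L)
    stopf("feature registry corrupted: %d features instead of 109", nrow(reg))
  if (anyDuplicated(reg$name))
    stopf("feature registry corrupted: duplicated names")
  required <- c("SUV_max", "SUV_mean", "MTV", "TLG", "CV", "Skewness",
                "NL_Entropy^GLCM", "NL_Homogeneity^GLCM",
                "NL_Dissimilarity^GLCM", "ZP^GLSZM", "HILZE^GLSZM")
  missing <- setdiff(required, reg$name)
  if (length(missing))
    stopf("feature registry corrupted: missing %s", paste(missing, collapse = ", "))
  reg
}

#' Extract the full 109-feature vector of a segmented tumor
#'
#' Quantizes the masked SUVs with the fixed-bin-width scheme, builds all nine
#' matrix families and returns exactly the registry's 109 features, in
#' registry order, all finite.
#'
#' @param volume a [suv_volume].
#' @param mask a [roi_mask] of the segmented tumor.
#' @param config optional list overriding quantization settings:
#'   `bin_width`, `range_min`, `range_max`, `n_levels` (see
#'   [quantize_fixed_bin_width]), `glcm_distance`, `ngldm_tolerance`.
#' @return Named numeric vector of length 109.
#' @examples
#' p <- make_tumor_phantom(phantom_spec(c(10, 10, 10), base_suv = 6,
#'                                      heterogeneity_sd = 0.3, seed = 3))
#' fv <- extract_all_features(p$volume, p$mask)
#' fv[c("SUV_max", "MTV", "NL_Entropy^GLCM")]
#' @export
extract_all_features <- function(volume, mask, config = list()) {
  cfg <- utils::modifyList(list(bin_width = 0.4, range_min = 0, range_max = 25,
                                n_levels = 64L, glcm_distance = 1L,
                                ngldm_tolerance = 0L, tfc_tolerance = 0L),
                           config)
  q <- quantize_fixed_bin_width(volume, mask, bin_width = cfg$bin_width,
                                range_min = cfg$range_min,
                                range_max = cfg$range_max,
                                n_levels = cfg$n_levels)
  tfc <- compute_tfc(q, a = cfg$tfc_tolerance)
  fv <- c(
    suv_statistics(volume, mask, levels = q$levels[q$mask_idx]),
    glcm_features(compute_glcm(q, distance = cfg$glcm_distance)),
    glrlm_features(compute_glrlm(q)),
    glszm_features(compute_glszm(q)),
    ngtdm_features(compute_ngtdm(q)),
    ngldm_features(compute_ngldm(q, a = cfg$ngldm_tolerance)),
    texture_spectrum_features(compute_texture_spectrum(q)),
    tfc_features(tfc),
    tfccm_features(compute_tfccm(tfc)))
  reg <- feature_registry()
  missing <- setdiff(reg$name, names(fv))
  if (length(missing))
    stopf("extractor did not produce registry feature(s): %s",
          paste(missing, collapse = ", "))
  fv <- fv[reg$name]
  bad <- names(fv)[!is.finite(fv)]
  if (length(bad))
    stopf("non-finite feature value(s): %s", paste(bad, collapse = ", "))
  fv
}
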