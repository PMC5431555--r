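---
title: "Methods: integrated PET radiomics phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated PET radiomics phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petradiomics)
```

# Overview

`petradiomics` implements an integrated radiomics analysis of FDG-PET tumor
volumes: a 109-feature texture panel per tumor, unsupervised hierarchical
clustering of patients by their whole radiomics pattern, and association of
the resulting tumor clusters with histopathology, pathologic complete
response (pCR) and disease-free survival (DFS). This vignette records the
model choices, parameter meanings and numerical conventions — in particular
every place where the underlying protocol left a decision open and the
package had to make one.

# Delineation and conventional indices

Tumors are delineated as the 26-connected component of `{SUV >= 2.5}`
containing an optional seed point, otherwise the largest component. The
threshold is closed (a voxel at exactly 2.5 is inside) so the mask is
deterministic across platforms. 26-connectivity is the most permissive
lattice connectivity and the standard in 3D lesion work. A volume in which
no voxel reaches the cutoff raises an explicit "undelineable tumor" error —
mirroring clinical practice, where such lesions are excluded rather than
segmented at a lower threshold. The seed point stands in for the operator's
manual localization of the primary lesion, which no automatic rule can
reproduce.

Conventional indices are computed on raw (unquantized) SUVs of the mask:
MTV (cm³) is the voxel count times the voxel volume; TLG = SUVmean × MTV;
CV = population SD / SUVmean. The identities `TLG = SUVmean * MTV` and
`MTV = n_voxels * voxel_volume` hold to numerical precision on every
extraction and are enforced by tests.

# Fixed-bin-width discretization

Gray levels are `floor((SUV - 0) / 0.4) + 1`, clipped to `[1, 64]`, i.e. a
fixed bin width of 0.4 SUV over the window 0–25. Note the arithmetic
tension in that convention: 25/64 = 0.390625, not 0.4, and 25/0.4 = 62.5.
The package treats **bin width 0.4 as authoritative** — it is the stated
intensity resolution, and a constant resolution across patients is the
point of the method — with Ng fixed at 64 and the top bin absorbing any
uptake at or above 25.2 SUV. Clipping (rather than extending the level
range) keeps the matrix dimensions constant across patients; clipped-voxel
counts are carried on the quantized object so the event is visible. Bins
are left-closed/right-open, so a voxel at exactly 0.4 maps to level 2. All
of `bin_width`, the range and `n_levels` are configuration keys.

# Texture matrices and the feature registry

All nine matrix families operate on the quantized lattice in index space
(voxel spacing enters only through MTV/TLG) and truncate neighborhoods at
the mask boundary, so background never contaminates a feature:

* **GLCM** — distance-1 co-occurrences over all 26 offsets summed into one
  symmetric matrix, then normalized. The `NL_` ("normalized") prefix on
  entropy/homogeneity/dissimilarity means *computed from the
  probability-normalized matrix* (counts/total), not range-rescaled to
  [0, 1]: observed clinical entropy values well above 1 bit rule the latter
  reading out. Entropies are in bits (log base 2).
* **GLRLM** — runs counted per 13 unique directions, matrices summed.
* **GLSZM** — zones are maximal 26-connected equal-level sets;
  `ZP = n_zones / n_voxels`, `HILZE = sum z(i,s) i^2 s^2 / n_zones`.
* **NGTDM** — per-level absolute deviation from the 26-neighborhood mean
  (in-mask neighbors only); the five Amadasun–King statistics, with an
  epsilon guard (1e-6) in coarseness and strength denominators.
* **NGLDM** — a neighbor is dependent when its level differs by at most a
  tolerance `a` (default 0); voxels without any in-mask neighbor are
  excluded rather than counted with dependence 0.
* **Texture spectrum** — each voxel's unit codes its 26 neighbors as
  less/equal/greater than the center. The cited original construction is
  two-dimensional (8 neighbors, 3^8 units); the package defines the 3D
  analogue with a hashed spectrum over observed units. Units come from
  interior voxels (all 26 neighbors in-mask) when any exist, else from all
  voxels with a valid neighbor with missing codes treated as "equal".
  Features are symmetry statistics chosen to be invariant under the 48
  axis symmetries of the lattice: black-white symmetry (swap less/greater),
  geometric symmetry (point reflection), degree of direction (axis
  transpositions), central symmetry of opposite pairs, mean per-axis
  flatness and its anisotropy, the equal-code fraction, and spectrum
  entropy.
* **TFC / TFCCM** — texture feature coding assigns each voxel a discrete
  code from the gradation classes of its 13 opposite neighbor pairs (both
  equal / one equal / monotone / extremum), scaled to 0–39; the TFCCM is
  the symmetric co-occurrence of codes over the 26-neighborhood with the
  usual co-occurrence statistics, including `Entropy^TFCCM`. A constant
  region codes to 0 everywhere; a strict 1D ramp collapses to the single
  monotone class.

The exact membership of the original 109-feature panel is not published in
any machine-readable form, so the package ships a **declarative registry**
(`feature_registry()`): 109 uniquely named features allocated as
Stats 18 / GLCM 22 / GLRLM 11 / GLSZM 11 / NGTDM 5 / NGLDM 6 /
texture-spectrum 8 / TFC 8 / TFCCM 20, constrained to include the eleven
features named individually in the clinical analysis (SUV_max, SUV_mean,
MTV, TLG, CV, Skewness, NL_Entropy^GLCM, NL_Homogeneity^GLCM,
NL_Dissimilarity^GLCM, ZP^GLSZM, HILZE^GLSZM). The registry is validated at
load and `extract_all_features()` refuses to emit anything that does not
match it exactly, with every value finite. Zero-variance conventions keep
the vector total: skewness, kurtosis and correlation-type features are 0 on
constant input rather than undefined.

Every matrix family is verified against an independent brute-force
enumerator (naive loops over voxels, pairs, runs, zones and neighborhoods)
on dozens of random small lattices, and all direction-aggregated features
are checked to be invariant under axis permutations of an isotropic region.

# The synthetic phantom generator

The generator is first-class code, not a fixture: an ellipsoidal lesion in
cold parenchyma whose uptake is `base_suv` modulated by a log-normal random
field — Gaussian white noise smoothed by an isotropic Gaussian kernel of
physical width `correlation_length`, normalized to unit variance inside the
lesion, scaled by `heterogeneity_sd` and exponentiated. Two parameters thus
control heterogeneity: its amplitude (the log-scale SD, approximately the
resulting CV) and its spatial scale. All randomness flows from explicit
integer seeds; generation never touches the global RNG state.

Three archetype templates emulate the published tumor-cluster phenotypes:

| archetype | target MTV (cm³) | target SUVmean | target CV |
|---|---|---|---|
| I (large, hot, heterogeneous) | 62.9 | 4.9 | 0.42 |
| II (mid, hot, heterogeneous) | 18.4 | 6.1 | 0.45 |
| III (small, mild, homogeneous) | 2.9 | 3.6 | 0.21 |

Calibration targets the published medians only (no distributional form is
available): semi-axes are the sphere-equivalent radii of the target
volumes, `base_suv` is the target mean deflated by the log-normal factor
`exp(sd²/2)`, and `heterogeneity_sd` equals the target CV.
`correlation_length` is not published anywhere; it was fixed once at 10 mm,
the value whose simulated per-archetype SUVmax medians (about 12 / 14 / 5.7)
best track the published 13.2 / 13.3 / 5.8. Per-patient spread comes from
15% log-normal multiplicative jitter on semi-axes and base SUV. Outcomes
are cluster-conditional: Bernoulli pCR (defaults 0.200 / 0.480 / 0.054),
exponential recurrence times per archetype hazard (defaults concentrate
events in archetype I, matching the published recurrence pattern),
right-censored by a uniform follow-up window of 24–57 months; clinical
markers (ER/PgR/HER2/Ki67/stage) are Bernoulli with per-archetype
probabilities taken from the published cluster-by-marker proportions.

What the phantoms do *not* emulate: scanner physics (PSF, attenuation,
reconstruction artifacts), respiratory motion, non-ellipsoidal shapes,
multifocality, and — importantly — the way clinical tumors concentrate
their co-occurrence mass. Under this generator the GLCM entropy of
archetype II plateaus near 7.7 bits for any correlation length (at CV 0.45
the level histogram alone spans ~28 of the 64 levels), above the published
per-cluster median of 5.8; archetypes I and III land inside the published
2.5–7.0 span. Passing tests therefore demonstrate correctness and ordering
of the machinery (entropy ordering III < I < II matches the clinical
ordering), not that phantoms are statistically indistinguishable from
patient data.

# Clustering

Features are z-scored with the **population** SD (the SD convention is not
published; population SD is the natural companion of the fixed cohort being
standardized) and clustered by Euclidean distance. The linkage criterion is
likewise unpublished. The package default is **Ward (`ward.D2`)**: its
within-cluster-variance objective matches z-scored Euclidean space, and in
planted-archetype recovery experiments (ten default cohorts of 10/25/37) it
recovers the planted partition with adjusted Rand index ≥ 0.8 in 9/10
cohorts where complete linkage manages 4/10 and average linkage 2/10 —
complete linkage chains the two hot archetypes, whose separation is carried
by many correlated size features. Complete and average linkage remain
available in the configuration.

The tree is cut at k = 3. Branches smaller than `min_cluster_size = 2` at
the cut are ejected as outliers and the tree is rebuilt among the rest —
the operationalization of the clinical practice of leaving a single
aberrant case (e.g. a delineation failure) out of every cluster. Cluster
labels are renumbered by first patient index so the assignment is invariant
to input order up to the partition itself.

The correlogram computes pairwise Pearson correlations with two-sided
p-values from the t transform, Bonferroni-corrected with the **feature
count** (109) as denominator — matching the published threshold of
p < 0.0005 = 0.05/109 rounded — rather than the pair count; the
denominator is configurable. Features are ordered by complete-linkage
clustering of the 1 − r distance; constant features have undefined
correlations and are masked out.

# Outcome statistics

* **2×2 odds ratios**: OR = ad/bc with Wald 95% CI
  `exp(ln OR ± 1.96·se)`, `se = sqrt(1/a + 1/b + 1/c + 1/d)`. The critical
  value is the conventional two-decimal 1.96 (the value clinical software
  reports with; `qnorm(0.975)` differs in the fourth decimal of the bound).
  Any zero cell triggers the Haldane–Anscombe +0.5 correction, recorded in
  the method tag. An all-zero row or column is an error, not a number.
* **Logistic regression** by IRLS (`stats::glm`); for a single binary
  covariate the fitted OR equals the closed-form 2×2 OR to 1e-6 — an oracle
  identity enforced by tests. Separation is detected (non-convergence or
  fitted probabilities collapsing to 0/1) and flagged on the result row.
* **Chi-square** proportions tests are Pearson without continuity
  correction, with expected counts reported.
* **Kaplan–Meier / log-rank** via the survival package; a cohort without
  events returns an explicit no-events result instead of a degenerate test.
  Simulated type-I error of the log-rank test at α = 0.05 is confirmed to
  lie in [0.03, 0.07] over 1000 null cohorts.
* **Cox regression** with Efron tie handling (monthly DFS granularity
  produces ties). Monotone partial likelihood — a covariate stratum with no
  events, as occurs in small cohorts with few recurrences — is flagged
  rather than reported as an ordinary estimate.

# Problem sizes and determinism

The test suite and the acceptance script regenerate everything from code:
default synthetic cohorts of 72 patients (10/25/37 per archetype) at the
clinical voxel spacing 3.91 × 3.91 × 3.27 mm, ten cohorts for recovery
experiments, 1000 null simulations for log-rank calibration and 200 cohorts
of n = 300 for Cox recovery — sizes at which every quantity is stable yet a
full run stays in the minutes range on a single core. Every stochastic step
draws from an explicit seed; the end-to-end pipeline writes byte-identical
summaries for identical configurations.

# Known limitations

* The registry's family allocation is the package's own reconstruction; a
  feature-by-feature match with the original panel cannot be verified
  against the main text and discrepancies are possible by design.
* Texture spectrum and TFC are 3D adaptations of constructions originally
  defined in 2D; their per-voxel codings are oracle-tested, but the feature
  formulas are this package's documented definitions.
* The fixed SUV 2.5 cutoff is known to mis-segment lesions with extreme
  heterogeneity or faint uptake; the package reproduces that behavior
  deliberately rather than correcting it.
* Cohort-dependent clinical quantities (per-cluster medians of a specific
  patient population, its hazard ratios and mean DFS) require the original
  cohort and are out of reach of the synthetic pipeline; the package
  reproduces the protocol, the table arithmetic and the statistical
  calibration, not the patient-level numbers.
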