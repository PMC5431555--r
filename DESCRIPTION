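Package: petradiomics
Title: Integrated PET Radiomics Phenotyping of Tumor Metabolic Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts 109 three-dimensional texture features from FDG-PET tumor
    volumes in SUV units (gray-level co-occurrence, run-length, size-zone,
    neighborhood gray-tone difference, gray-level dependence, texture spectrum
    and texture-feature-coding matrices, plus SUV histogram statistics),
    delineates tumors by a fixed SUV threshold, discretizes uptake with a fixed
    bin width, clusters patients by their radiomics pattern with hierarchical
    clustering and outlier ejection, and associates the resulting tumor
    clusters with histopathology, pathologic complete response and
    disease-free survival (odds ratios, logistic regression, Kaplan-Meier,
    log-rank and Cox models). Ships a synthetic tumor-phantom generator that
    emulates three breast-tumor archetypes so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    survival,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
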