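Package: rtfrel
Title: Reliability of Radiomic Texture Features from Cardiac Parametric Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the repeatability and reproducibility of radiomic
    texture features (RTFs) extracted from 2D parametric maps such as cardiac
    T1 maps. Implements a 93-feature texture engine (first-order statistics
    plus the GLCM, GLRLM, GLSZM, GLDM and NGTDM matrix families) applied to
    eleven image versions (original plus ten filters), a three-mask consensus
    intersection-over-union decomposition, two-way ANOVA intraclass
    correlation estimation with F-based confidence intervals and four-tier
    categorization, degenerate-feature screening, and a segmentation
    perturbation model for sweeping mask variability. A synthetic phantom
    cohort generator emulating paired-field-strength annular myocardial ROIs
    makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    igraph,
    EBImage,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
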