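Package: lmhocta
Title: OCT-Angiography Microvascular Quantification for Lamellar Macular Holes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for en-face OCT-angiography of lamellar
    macular holes: binary vessel and perfusion maps from a fused global
    threshold, multiscale Hessian vesselness filter and adaptive threshold;
    foveal/parafoveal sector-grid vessel and perfusion densities; capillary
    free zone morphometry (area, perimeter, circularity); longitudinal
    foveal tissue-loss quantification and progressive-versus-stable
    classification; and the accompanying small-sample statistical battery
    (Shapiro-Wilk gated tests, exact Mann-Whitney and Wilcoxon, permutation
    Spearman, Fisher exact, two-way ICC). A synthetic-data module generates
    angiograms with known ground truth and two-group cohorts so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
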