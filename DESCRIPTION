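Package: dimstab
Title: Pre-Analytical Stability Assessment for Direct-Infusion Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the pre-analytical stability of small-molecule
    metabolites in biofluids measured by direct-infusion high-resolution mass
    spectrometry. Starting from called peak lists, the package annotates peaks
    against a metabolite mass library within a ppm tolerance across five adduct
    channels, sums adduct intensities into one value per metabolite annotation,
    quantifies technical (analysis) variability from spiked stable
    isotope-labelled compounds (coefficient of variation and median absolute
    variation), classifies storage-condition effects by comparing per-condition
    fold-change confidence intervals against the analysis-variability band, and
    runs a per-feature statistical battery (PCA, repeated-measures ANOVA,
    Kruskal-Wallis, Bonferroni correction). A synthetic-data module emulates a
    pooled-biofluid storage-stability study design (freeze/thaw cycles and
    storage at -20 C, 5-8 C and 18-22 C) with known injected effects, so the
    whole pipeline is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
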