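Package: senoscope
Title: Multiparametric Imaging Analysis of Cellular Senescence Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for organelle-level profiling of cellular
    senescence from fluorescence microscopy. Converts masked single-cell
    images into area-normalised intensity densities (a.u. per square
    micrometre), builds log-spaced per-cell-averaged intensity histograms and
    detects lysosomal subpopulation peaks by prominence and minimum distance,
    models peak positions with a linear mixed model (donor, inducer and peak
    order as fixed effects, a per-curve random intercept), compares
    distribution shapes across donors with the k-sample Anderson-Darling test
    under Benjamini-Hochberg control, segments mitochondrial membrane
    potential distributions at data-driven inflexion points of the cumulative
    distribution into depolarised, mid and hyperpolarised fractions, and
    scores senescence induction with the SA-beta-Gal positive fraction,
    relative survival and selectivity index. A synthetic-data generator with
    known ground truth emulates the study designs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    lme4,
    lmerTest,
    car,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pbkrtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
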