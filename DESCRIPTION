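Package: furrowquant
Title: Quantification of Basal Myosin-II Dynamics and Apical Constriction
    During Epithelial Invagination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for time-lapse fluorescence
    microscopy of epithelial morphogenesis, modeled on optogenetic
    perturbation experiments of basal myosin-II during Drosophila ventral
    furrow formation. Provides a synthetic-microscopy generator with known
    ground truth (columnar-to-wedge cell geometry at constant volume,
    decaying or saturating basal myosin layers, constricting actomyosin
    ring fields, pulsatile apical-area traces), membrane segmentation and
    overlap-based cell tracking, axial (z-profile) Gaussian quantification
    of basal and apical myosin levels, circular-Hough detection of basal
    actomyosin rings with constriction-speed and ring-density statistics,
    3D cell-shape feature extraction (length, apical/basal area, A/B
    ratio, volume) from label volumes, pulsatile/ratchet constriction
    analysis of apical-area time series, and the accompanying statistical
    layer (two-sample t-test, one-way ANOVA with Tukey HSD, Cohen's d with
    a maximal-SD convention, boxplot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
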