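Package: sfdiskin
Title: Spatial Frequency Domain Imaging of Skin Optical Properties
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end spatial frequency domain imaging (SFDI) analysis
    chain for in vivo skin: three-phase demodulation of patterned-illumination
    image stacks, calibration against a reference phantom of known optical
    properties, lookup-table inversion of calibrated diffuse reflectance to
    per-pixel absorption and reduced scattering coefficients under a
    semi-infinite homogeneous diffusion model, and penetration-depth
    estimation. A layered Monte Carlo photon-transport oracle validates the
    diffusion forward model. A synthetic cohort generator renders
    ground-truthed layered-skin acquisition stacks spanning Fitzpatrick skin
    types I-VI and ten anatomic locations, reproducing the epidermal-melanin
    confound that inflates intersubject reduced-scattering variation at short
    wavelengths. Cohort statistics (ROI aggregation, coefficient of
    variation, one-way ANOVA, Tukey HSD) can be computed from raw maps or
    reconstructed from printed summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'chromophores.R'
    'cohort-stats.R'
    'tissue-model.R'
    'cohort.R'
    'demodulate.R'
    'forward-model.R'
    'invert.R'
    'io.R'
    'monte-carlo.R'
    'render.R'
    'pipeline.R'
    'tables.R'
    'zzz.R'
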