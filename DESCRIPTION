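Package: ramanpe
Title: Micro-Raman Quantification of Polyethylene Phase Composition and Wear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the phase composition (orthorhombic, amorphous, and
    intermediate "third" phase) and trans-conformer content of ultra-high
    molecular weight polyethylene from micro-Raman spectra, as used to
    characterize wear of acetabular cups tested on hip-joint simulators.
    Provides spectrum I/O (two-column ASCII and JCAMP-DX), baseline
    correction, pseudo-Voigt curve fitting of overlapped band regions,
    windowed band integration with tail-capture correction, the
    Strobl-Hagedorn phase equations and Lagaron/Naylor conformer equations,
    molecular-orientation checks, soak-corrected gravimetric wear, and
    nonparametric cohort statistics (exact-permutation Kruskal-Wallis with
    Dunn-Bonferroni post hoc and compact letter displays). A synthetic
    spectrum generator with known ground truth supports end-to-end
    validation and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
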