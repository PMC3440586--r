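Package: asmbrain
Title: Active-Shape-Model Quantification of Brain Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated quantification of regional cerebral blood flow
    (rCBF) SPECT volumes. A point-distribution model (mean landmark shape plus
    principal-component modes of brain-shape variation) is fitted to a
    reconstructed SPECT volume with the active-shape algorithm; maximal
    cortical counts are projected onto surface sample points, normalized to
    cerebellar or whole-cortex reference values, and aggregated into lobar
    regional means, left-right asymmetry indices and a cortical index.
    Includes a digital brain-phantom simulator (shape variability, partial
    compartments, PSF blur, Poisson counting noise) for validation and for
    building synthetic normal-value databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
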