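Package: retphen
Title: Retinal Phenotyping: Vessel Caliber, ERG Waveform Analysis, and OCT Layer Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative retinal phenotyping tools for rodent studies:
    a hybrid flat-mount vessel-caliber algorithm (centerline thinning,
    perpendicular intensity slices, reference-circle clipping, ensemble
    averaging, mid-brightness width), electroretinogram waveform analysis
    (A/B-wave features, Naka-Rushton intensity-response fits, Lamb-Pugh
    phototransduction activation fits, FFT separation of oscillatory
    potentials), optical coherence tomography layer-thickness sampling at
    fixed lateral distances from the optic disc, and a cohort pipeline that
    emits per-animal tables and mean +/- SEM group summaries. Includes
    synthetic-data generators with analytic ground truth for validation.
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
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
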