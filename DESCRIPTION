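Package: oligofit
Title: Mass-Action Oligomerization Equilibria, SEC-MALS Binding Analysis
    and CD Thermal Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying protein homo-oligomerization from
    solution biophysics. Defines stepwise mass-action assembly schemes
    (monomer-trimer coiled coils, obligate-dimer to tetramer to hexamer
    ladders), solves their equilibria, predicts the weight-average
    molecular weight observed by size-exclusion chromatography with
    multi-angle light scattering (SEC-MALS), and fits schemes to
    dilution-series binding data with apparent-Kd extraction and
    bootstrap confidence intervals. Converts raw SEC-MALS detector
    traces (light scattering, differential refractive index) into
    per-injection binding points. Processes circular dichroism spectra
    (Savitzky-Golay smoothing, mean-residue normalization,
    secondary-structure deconvolution) and fits one- or two-transition
    two-state van't Hoff models to 222 nm thermal melts. A synthetic
    data module generates every input the pipeline consumes, at desk
    scale, for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
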