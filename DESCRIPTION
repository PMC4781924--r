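Package: mplmfit
Title: Quantitative Spectral Unmixing by Multi-Pass Local Mesh Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Beer's-law quantitative analysis of mixture absorbance spectra
    (FTIR and similar linear spectroscopies). Component concentrations are
    found by direct minimisation of the root-mean-square residual between a
    measured mixture spectrum and a concentration-weighted sum of reference
    component spectra, either by exhaustive evaluation on a fixed
    concentration mesh (single mesh method, SMM) or by a fast multi-pass
    local adaptive mesh refinement search (MPLM). Includes goodness-of-fit
    diagnostics, a concentration-matched reference re-fit rule for aqueous
    samples, seeded synthetic spectrum generators for validation, and
    downstream analyses: fermentation time-series tracking, protonation-state
    pH estimation via two-endpoint unmixing, and two-chamber membrane
    permeability estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'grid-search.R'
    'unmix-core.R'
    'applications.R'
    'synthetic.R'
    'cli.R'
    'spectra-io.R'
    'jcamp.R'
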