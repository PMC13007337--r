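Package: odortrace
Title: Odor-Evoked Calcium Imaging Analysis for Olfactory Bulb Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell odor-response calcium imaging
    of the teleost olfactory bulb. Extracts ROI fluorescence traces from
    multi-page TIFF movie stacks, converts them to trial-averaged, low-pass
    filtered dF/F, quantifies odor-evoked response magnitudes, detects
    significant responses by a 6-standard-deviation peak criterion, assigns
    preferred stimuli, computes lifetime sparseness tuning indices, builds
    sorted population heat maps and frame-subtraction spatial activity maps,
    and runs the accompanying group statistics (per-volume count
    normalization, Holm-Sidak corrected t-test families, two-way repeated
    measures ANOVA with Sidak post-hoc comparisons). Includes a synthetic
    nuclear-GCaMP movie generator with known per-cell tuning, kinetics,
    noise and drift that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    signal,
    yaml,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
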