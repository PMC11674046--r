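Package: nucloc
Title: Quantification of Intranuclear Receptor Localization and Nuclear
    Export from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and quantitative analysis of multi-channel
    fluorescence micrographs for assays of nuclear export receptor
    biology. Provides a synthetic scene generator with per-cell ground
    truth, nucleus/cell-body/compartment segmentation, per-cell intensity
    ratiometrics (compartment/nucleoplasm, nuclear/cytoplasmic and
    nuclear/total cargo ratios), composite Cajal-body and nucleolar
    localization scores normalized to a reference condition, an
    expression-controlled nuclear export assay, and Student's t based
    condition-versus-reference reporting with figure-style significance
    labels.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: CellBiology, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'nucloc-package.R'
    'AllClasses.R'
    'segment-quant.R'
    'export-assay.R'
    'imaging-io.R'
    'localization-score.R'
    'scene-sim.R'
    'presets.R'
    'stats-report.R'
    'pipeline.R'
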