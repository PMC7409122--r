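Package: mobiquant
Title: Targeted Small-Molecule Quantification from MALDI Ion-Mobility MS/MS
    Acquisitions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end computational pipeline for a MALDI ion-mobility
    tandem-MS assay quantifying a small-molecule drug (osimertinib) in human
    plasma. Implements extracted-ion-mobilogram peak integration (MobA) and
    combined-spectrum peak intensities (MassI), internal-standard-normalized
    responses, 1/x^2-weighted linear calibration with EMA/FDA curve
    acceptance, a bioanalytical validation engine (sensitivity, precision and
    accuracy, specificity, carry-over, dilution-compensated recovery,
    IS-normalized matrix factors, freeze/thaw bookkeeping), and incurred-
    sample cross-validation against a reference method. A synthetic
    acquisition generator reproduces the assay's signal structure (2D
    Gaussian fragment peaks in m/z and drift time, a near-isobaric
    interferent, V/W resolution modes, spot heterogeneity) so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'study_design.R'
    'synthetic.R'
    'mobilogram.R'
    'calibration.R'
    'validation.R'
    'crossval.R'
    'io.R'
    'campaign.R'
    'mobiquant-package.R'
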