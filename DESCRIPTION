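Package: ecgsynth
Title: Mechanistic Synthesis of Labeled 12-Lead ECGs from Cardiac
    Electrophysiology Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates labeled synthetic 12-lead electrocardiograms from
    mechanistic electrophysiology simulations on parametric idealized
    cardiac anatomies. Atrial P waves and ventricular QRST complexes are
    simulated separately with an anisotropic Eikonal activation model, a
    Mitchell-Schaeffer reaction-Eikonal transmembrane voltage construction,
    and an infinite-volume-conductor dipole forward model, then assembled
    into 10 s, 500 Hz records with Gaussian-conditional amplitude and
    interval coupling, a power-law heart-rate-variability model, realistic
    composite noise, and Butterworth bandpass filtering. Seven pathology
    families (myocardial infarction with six sub-classes, bundle branch
    block, fibrotic atrial cardiomyopathy, interatrial conduction block,
    left atrial enlargement, first-degree AV block) are produced as
    mechanistic modifiers with exact ground-truth labels and fiducials,
    and records are written in a 12-row CSV dataset layout with
    anatomy-disjoint train/validation/test splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lhs,
    Matrix,
    signal,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
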