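Package: condensatr
Title: Analysis Toolkit for Engineered Protein Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for characterising liquid-liquid phase
    separation of engineered repeat-protein condensates. Provides
    direct-coexistence slab-trajectory analysis (density profiles,
    coexisting-phase densities, binodal and critical-temperature fitting via
    the law of coexisting densities and the law of rectilinear diameters),
    intermolecular residue-contact and molecular-valency analysis of
    coarse-grained trajectories, sedimentation-assay saturation-concentration
    fitting with gel-band calibration, droplet-microfluidic phase-diagram
    construction with probability maps and boundary extraction, and
    fluorescence-image partition-coefficient analysis with Triangle
    thresholding. Ships synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    Rcpp,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d,
    seqinr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
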