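Package: vinlock
Title: Two-Step Vinculin Unlocking: Interfaces, Ion-Mobility Conformers and
    Focal-Adhesion Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the two-step unlocking of the vinculin
    head-to-tail autoinhibitory interaction. Reads protein structures and
    quantifies domain-domain interfaces (buried solvent-accessible area,
    hydrogen-bond censuses), maps single-residue anchoring spots in surface
    cavities, computes projection-approximation collision cross sections
    (CCS) and builds rigid-body semi-open/open conformer models, calibrates
    traveling-wave ion-mobility drift times against CCS standards, analyses
    native electrospray charge-state envelopes and conformer ensembles,
    detects closed/semi-open/open states and their transitions in
    collision-induced unfolding fingerprints, and quantifies focal-adhesion
    morphology and Y27632-response decay kinetics. A deterministic
    synthetic-data generator emulates the instrument and microscope inputs
    so that every analysis step is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    jsonlite,
    yaml,
    tiff,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
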