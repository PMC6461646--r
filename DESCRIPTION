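Package: nucleomech
Title: Quantification of Nuclear Mechanics from Microscopy and Gel Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image- and trace-quantification pipelines for studying how
    actomyosin activity compresses the nucleus and condenses chromatin:
    sensitized-emission FRET index maps with donor-leakage and
    cross-excitation calibration, double-normalized fluorescence recovery
    after photobleaching (FRAP) curves with exponential recovery fits,
    3D nuclear volumetry and 2D circularity from anisotropic confocal
    z-stacks with watershed splitting of touching nuclei, and DNase I gel
    densitometry with ladder-based fragment-size calibration. A synthetic
    ground-truth generator (nuclei stacks, FRET scenes, FRAP traces, gel
    images) makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
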