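Package: midfacer
Title: Virtual Reconstruction of Bony Midfacial Defects with a Conditional GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for GAN-based virtual reconstruction of bony
    midfacial defects on CT volumes. Generates skull-like head phantoms with
    five labelled midfacial subunits, carves parametric artificial defects
    (sphere, cuboid, semi-cylinder), trains a conditional generative
    adversarial network to inpaint defect slices, and quantifies accuracy by
    cosine similarity of 8-bit slice images and registered mean surface error
    (mm) against a mirror-symmetry reference, with Mann-Whitney group
    comparison and table-style reporting. Includes a minimal axial CT DICOM
    reader/writer, marching-tetrahedra surface extraction, and iterative
    closest point rigid registration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
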