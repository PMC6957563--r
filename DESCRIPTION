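Package: negmap
Title: Behavioral, ROI, and Cytoarchitectonic Analysis of Logical
    Negation Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for dissociating logical negation from
    language and numerosity. Implements the net negation interaction
    (NetNegInt) statistic on reaction times and BOLD percent signal
    change, repeated-measures inference on a 2x2 within-subject design,
    a Weber's-law Gaussian-fit comparison on linear versus
    log-compressed proportion axes, a three-parameter Gaussian
    decomposition of the negation cost with permutation inference,
    behavior-BOLD coupling, volume-overlap metrics between functional
    clusters and probabilistic cytoarchitectonic maps, and the
    observer-independent border-detection procedure based on grey-level
    index profiles and a sliding-window Mahalanobis distance. Includes
    synthetic-data generators (trial tables, percent signal change,
    laminar histology phantoms, voxel volumes) with known ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
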