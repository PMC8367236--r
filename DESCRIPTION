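Package: psoctfib
Title: Detection and Quantification of Subretinal Fibrosis in
    Polarization-Sensitive OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to detect, segment and quantify birefringent subretinal
    fibrotic lesions in three-dimensional polarization-sensitive optical
    coherence tomography (PS-OCT) volumes.  The pipeline extracts
    reflectivity, retardation, axis orientation and the degree of
    polarization uniformity (DOPU) from two-channel complex tomograms,
    numerically compensates the birefringence of anterior ocular
    structures (cornea, retinal nerve fiber layer, Henle's fiber layer)
    by Jones calculus, computes masked depth-averaged optic-axis
    orientation maps, and segments lesions by circular-variance seeded
    region growing with areal quantification, threshold-sweep likelihood
    maps and axis-variance B-scans.  A layered digital eye phantom with
    full ground truth makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
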