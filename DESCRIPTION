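Package: mothatlas
Title: Standard Insect Brain Construction, Neuron Tracing and Landmark
    Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building a standard (average) insect brain from
    confocal image stacks and registering neuron morphologies into it.
    Provides readers and writers for SWC neuron morphologies, multi-page
    grayscale TIFF stacks, Wavefront OBJ surface meshes and named-landmark
    CSV tables; landmark-based rigid, affine and 3D thin-plate-spline
    transforms applied to points, morphologies and image volumes; an
    average-brain (atlas) construction pipeline with binarization and
    surface extraction; a region-growing neurite tracer with scripted
    corrective edits; a synthetic cylinder-tree phantom generator with
    exact ground truth under four image-corruption conditions; tracing
    accuracy metrics (branch consistency, diameter discrepancy, landmark
    and registration error); a passive compartmental cable model for
    electrical validation of reconstructions; and overlap-volume
    estimation of putative connectivity between registered arbors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
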