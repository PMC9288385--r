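Package: perivasc
Title: Perivascular and Retinal Microvascular Image Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for fluorescence-microscopy studies of
    cerebral small-vessel disease. Implements retinal flat-mount vessel
    morphometry (Phansalkar local thresholding, topology-preserving
    skeletonisation with distance-transform radii, tortuosity and branching
    index), perivascular concentric-ring signal densities with a
    no-double-counting assignment rule, blood-brain-barrier tracer
    line-profile analysis, vessel-marker coverage, immunogold particle
    densities per reconstructed cell volume, and the group-comparison
    statistics used for such data. A synthetic-image generator with planted
    ground truth (vessel trees of known diameter, tortuosity and branch
    count; perivascular marker profiles; tracer leak levels; Poisson
    particle counts) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, Visualization, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
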