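Package: censpa
Title: Single-Particle Averaging of Centromere Geometry from 3D Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to measure the core three-dimensional geometry of human
    mitotic centromeres by single-particle averaging of multi-channel 3D
    fluorescence image stacks. Includes a calibrated forward simulator of
    paired CENP-A clusters, the pericentromeric cohesin axis and the
    alpha-satellite DNA cloud (with Poisson and camera noise and per-particle
    ground truth); sub-pixel 3D Gaussian spot refinement; rotational particle
    alignment, mirroring and averaging; multi-Gaussian intensity-profile
    fitting with AIC model selection; center-enriched ratio classification of
    cohesin patterns with Kruskal-Wallis comparisons; and a genomic-interval
    module for replicate-consensus peaks, per-region peak densities, mapped
    read proportions and overlap fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    minpack.lm,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
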