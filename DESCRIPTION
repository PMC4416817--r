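Package: nucarch
Title: Quantitative Nuclear Architecture Analysis for Preimplantation Embryo 3D-SIM Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying nuclear architecture remodelling in
    3-D structured illumination microscopy stacks of preimplantation
    embryo nuclei, together with an intron-coverage statistic for
    detecting embryonic genome activation in RNA-seq data. Provides
    seven-class equal-variance voxel intensity classification of DNA
    staining, enrichment and depletion statistics of a nuclear pore
    marker across intensity classes, nucleus segmentation and volume
    censuses, lamina-shell extraction with nuclear pore / chromatin
    contact concordance, detection and immunophenotype classification of
    nuclear envelope invaginations, vesicles and extranuclear clusters,
    and the RINP (reads in intronic regions per not-covered intronic
    position) statistic. A ground-truthed synthetic data generator
    emulates pre- and post-genome-activation nuclear phenotypes, mitotic
    chromatin plates and spliced/unspliced read alignments so that every
    stage of the pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
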