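Package: nucdis
Title: Transcription-Coupled Nucleosome Disassembly from ChIP Occupancy Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-level quantification of ChIP coverage (IP/INPUT log2 ratios
    over ORFs), scale-regions metagene profiling, k-means gene classification,
    gene-set overlap and correlation statistics, and a steady-state
    decomposition model of RNA-polymerase-II-coupled nucleosome disassembly
    (D = L + R) with a correlation-maximisation grid-search estimator of a
    chromatin remodeller's relative contribution to disassembly. Includes a
    fully parameterised synthetic-cohort generator with latent ground truth
    so every stage of the pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, NucleosomePositioning, Transcription,
    Coverage, Software
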