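Package: coreshell
Title: Multiplexed FISH Quantification and Core/Shell Cell Typing of the Claustrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for multiplexed single-molecule
    fluorescent in situ hybridization (mFISH) analysis of excitatory
    claustrum subtypes: iterative-round DAPI-anchored rigid plus elastic
    image registration, nuclei segmentation with somatic ROI expansion,
    percent-area-covered (PAC) quantification with histogram-tail
    binarization, UMAP embedding and Leiden clustering into core, shell
    and cortical phenotypes, retrograde projection (RSC/LEC) contingency
    analysis, and a single-cell RNA-seq CPM quality-control module. A
    synthetic-data generator with full ground truth stands in for raw
    images and count matrices so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    uwot
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
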