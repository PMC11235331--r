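Package: txdemux
Title: Donor and Recipient Demultiplexing of Transplant Single-Cell RNA-Seq by Expressed SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segregates donor-genotype from recipient-genotype cells in
    transplant single-cell RNA-seq experiments using expressed single
    nucleotide variants, without matched germline genotyping. Implements a
    two-stage genotype discovery method robust to extreme donor/recipient
    imbalance: community clustering of a k-nearest-neighbour graph over
    allele-fraction distances, followed by a median-absolute-deviation
    rescue of rare second genotypes, and iterative refinement with
    simulated-doublet calibration. Includes a droplet transplant-mixture
    simulator with doublets and collapsed-molecule ambient RNA swapping,
    selection of compact genotype-predictive SNV panels with dot-plot
    summaries, and TPR/FDR/ARI benchmarking against ground truth. Reads and
    writes cellSNP-style sparse allele-count inputs and exports the input
    layouts of other demultiplexers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
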