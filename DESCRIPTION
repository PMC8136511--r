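Package: lbagrid
Title: Sensitivity Analysis of Long-Branch Attraction in Phylogenomic
    Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting long-branch attraction (LBA) in phylogenomic
    data sets by systematically varying gene occupancy and taxonomic sampling.
    Builds occupancy-by-pruning supermatrix grids with partition bookkeeping,
    bins loci into evolutionary-rate tertiles by mean pairwise sequence
    identity, computes gene-wise log-likelihood differences (deltaGLS) between
    competing placements with a self-contained amino-acid likelihood engine
    (empirical exchangeability models, discrete-gamma rate heterogeneity,
    Felsenstein pruning, branch-length optimisation, BIC model choice),
    classifies the sister group of a focal clade across a sensitivity grid,
    simulates Felsenstein-zone and clade-structured LBA scenarios, and analyses
    rare genomic changes: Fitch parsimony with ACCTRAN/DELTRAN resolutions,
    LCA gene-tree/species-tree reconciliation for shared whole-genome
    duplications, paralog screening, and duplication tally matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
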