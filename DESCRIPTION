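Package: crisisgraph
Title: Joint Junction-Balanced Genome Graphs for Post-Crisis Clone Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing structural-variant evolution in clonal
    cell populations that escaped telomere crisis. Builds junction-balanced
    genome graphs from binned read depth and rearrangement junction calls,
    jointly infers integer copy numbers across a compendium of related clones
    with a mixed-integer program that penalizes unique loose ends, decomposes
    balanced graphs into walks (reconstructed alleles), clusters clones by
    copy-number profile, derives clone phylogenies from somatic SNVs,
    phases parental haplotypes through single-allele loss, detects
    kataegis-like SNV clusters, and screens loose ends for telomere-repeat
    content. Includes a breakage-fusion-bridge / chromothripsis simulator
    that generates ground-truthed clone compendia for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
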