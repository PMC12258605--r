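Package: nlrscape
Title: Domain Architecture, Genomic Clustering and Nucleotide-Binding
    Domain Typing of Fungal NLR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising repertoires of fungal NOD-like
    receptors (NLRs) from protein sequences and gene annotations:
    resolution of competing profile-HMM domain hits with a priority and
    squared-E-value rule, calling of candidate NLRs with canonical
    tripartite architectures, classification of nucleotide-binding (NB)
    domains into NB-ARC, T-NACHT and N-NACHT types using degenerate
    Walker B and HETHS consensus motifs, alignment-free k-mer and
    Lempel-Ziv distances between NB fragments with principal coordinates
    analysis, detection of genomic NLR clusters with a permutation-null
    calibration of the distance and intervening-gene parameters,
    head-to-head pair detection, and phylogenetic generalized least
    squares for associations between repertoire size and genome
    features. Includes simulators for every input the pipeline consumes
    (gene tables with planted clusters, proteins with planted motifs,
    domain-hit tables, Brownian-motion traits on a tree), so the whole
    analysis is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    GenomicRanges,
    nlme,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
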