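Package: mirfam
Title: Homology-Based Discovery and Characterization of Plant miRNA Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of the computational workflow used to
    discover and characterize conserved plant microRNA families (such as miR166)
    from genome scaffolds: Smith-Waterman homology scanning for candidate
    precursor loci, energy-weighted Nussinov hairpin folding with MFE/MFEI
    screening, mature-arm annotation against reference sets, UPGMA phylogenetics
    with bootstrap support, promoter cis-element prevalence summaries,
    expectation-scored miRNA target prediction, DICE/Nei similarity clustering of
    target-function profiles, and 2^-ddCt stem-loop RT-qPCR fold-change analysis
    with Tukey significance letters. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
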