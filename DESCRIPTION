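Package: cnsevol
Title: Conserved Noncoding Sequence Detection and Rate-Acceleration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls conserved noncoding elements (CNSs) from multi-species
    genomic alignments using a rejected-substitutions score against a neutral
    species tree, computes the mean pairwise nucleotide substitution frequency
    of each element, detects rapidly evolving and species-specific rapidly
    evolving regions with dispersion-corrected chi-squared tests, classifies
    regions by genomic context relative to gene models (upstream, 5'UTR,
    intron, 3'UTR, downstream), and runs hypergeometric term enrichment on
    associated genes. Includes a Jukes-Cantor alignment simulator along a
    species tree with known conserved, neutral and lineage-accelerated
    segments so that every stage of the analysis can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
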