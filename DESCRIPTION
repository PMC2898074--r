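Package: asmirmask
Title: miRNA Binding-Site Depletion in Sense-Antisense Overlap Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Genome-scale analysis of predicted microRNA binding sites in
    natural antisense transcript (NAT) pairs. Maps the pairing (sense-antisense
    overlapping) and non-pairing regions of each transcript pair by local
    alignment, predicts miRNA binding sites with a miRanda-style two-phase
    scanner (seed-weighted complementarity alignment with G:U wobble, then a
    nearest-neighbor RNA:RNA duplex free-energy filter), normalizes site counts
    to per-nucleotide densities, and tests for depletion of sites in the
    overlap with a Wilcoxon rank-sum test and a Monte Carlo randomization null
    (P = x/1,000). Includes a synthetic pair-set generator with planted sites
    at controlled per-nucleotide rates, and mono- and dinucleotide-preserving
    sequence shufflers, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
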