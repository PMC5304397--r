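Package: dupdyn
Title: Duplicate-Gene Dynamics: Gene Family Clustering, Paralog Dating
    and Birth-Death Family-Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics toolkit for studying gene duplication
    and loss between related genomes, built around the analyses used to
    characterise genome streamlining in aphids.  Clusters proteins into
    gene families with a Markov Cluster (MCL) implementation on filtered
    all-against-all similarity hits; dates paralog pairs by pairwise
    synonymous divergence using Nei-Gojobori (NG86) codon counting with
    Jukes-Cantor correction; classifies duplicates as pre- or
    post-speciation against the mean dS of 1:1 orthologs and computes
    ancestral-duplicate loss rates; fits lambda birth-death models of
    gene family size on a timetree with nested-model likelihood-ratio
    tests and maximum-likelihood ancestral family sizes; calls tandem
    arrays from gene order; and provides the enrichment statistics
    (2x2 chi-square, Mann-Whitney U), the differential-expression filter
    chain (quantile pre-filter, negative-binomial test, Benjamini-Hochberg
    FDR, fold-change call) and 2^-deltaCt quantification used to link
    expression plasticity to duplicated gene categories.  Includes
    simulators with known ground truth for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
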