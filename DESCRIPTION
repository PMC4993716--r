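Package: rflptools
Title: Virtual RFLP Profiling, Clustering and Diversity Statistics for
    Aligned 16S rRNA Gene Sequences
Version: 0.1.0
Authors@R:
    person("RFLP", "Tools Developers", email = "rflptools@example.org",
           role = c("aut", "cre"))
Description: In-silico restriction digestion of aligned marker-gene
    sequences with degenerate (IUPAC) recognition sites, virtual-gel band
    profiling, binary site/band presence-absence matrices, Jaccard
    similarity with UPGMA dendrograms, principal component ordination of
    binary profiles, Mandel's h and k consistency statistics with critical
    values, and DnaSP-style nucleotide polymorphism summaries (segregating
    sites, haplotype and nucleotide diversity, four-gamete minimum
    recombination). Includes a seeded generator of group-structured
    synthetic alignments with plantable restriction sites, so the whole
    pipeline is testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
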