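Package: mhc2div
Title: Single-Locus MHC Class II Exon-2 Allelic Diversity Analysis
Version: 0.1.0
Authors@R: person("MHC", "Diversity Toolkit Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of allelic diversity at a single MH (major
    histocompatibility) class II beta-chain locus from in-frame exon-2 codon
    alignments and diploid genotype panels: polymorphism and heterozygosity
    summaries, pathway-averaged Nei-Gojobori dN/dS with Jukes-Cantor
    correction partitioned by peptide-binding sites, bootstrap Z-tests of
    positive selection, GY94 codon site models (M7 beta-neutral versus M8
    positive-selection class) with likelihood-ratio testing and per-site
    selection posteriors, Hardy-Weinberg exact tests, permutation tests of
    allelic co-occurrence with sequential Bonferroni correction, EM haplotype
    phasing of degenerate diploid sequences, Mendelian inheritance checking
    in nuclear families, minimal-cost mosaic recombination scanning with
    permutation significance, and minimum-spanning haplotype networks.
    Includes a seed-deterministic synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
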