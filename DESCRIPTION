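Package: ratchet
Title: Comparative Genomics of Endosymbiont Genome Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two closely related strains of a reduced,
    vertically transmitted bacterial endosymbiont: synteny-aware one-to-one
    homolog pairing with orphan calling, pseudogene detection from translated
    similarity in unannotated intergenic DNA, intergenic synteny and decay
    analysis, nucleotide-composition statistics (GC, GC2, GC4, RSCU and the
    codon adaptation index) with ANOVA and Tukey HSD group comparisons,
    per-gene protein and codon-level nucleotide divergence metrics, and a
    seeded ancestor-to-descendants genome-pair simulator with ground truth so
    the whole pipeline can be exercised without external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    methods,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
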