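Package: retropap
Title: Assembly-Based Genotyping of Retrotransposon Presence/Absence
    Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for genotyping presence/absence
    polymorphisms (PAPs) of retrotransposon Gag-like elements across multiple
    genome assemblies of related accessions.  Provides k-mer seed-and-chain
    local alignment with alignment-ratio scoring of element loci, reciprocal
    best-hit orthology with CNV/PAP classification, depth-based contig
    splitting and hint-guided scaffold joining, fruit-ripening-inducible
    expression classification with Pearson co-expression of element-flanking
    genes, Fisher exact term enrichment, and a fully seeded synthetic-genome
    simulator with ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
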