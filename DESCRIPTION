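Package: hapcompare
Title: Intra-Haplotype Divergence Analysis for Phased Diploid Genome
    Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares the two haplotype assemblies of a phased diploid
    genome. Partitions the haplotypes into syntenic, inverted,
    translocated, inserted/deleted, highly diverged and
    haplotype-unique regions using unique k-mer anchor chains; detects
    and categorizes hemizygous (haplotype-specific) genes; pairs
    identical one-to-one homologs by exact coding-sequence equality;
    tests inter-haplotype differential expression across tissues; and
    quantifies promoter variant burden of differentially expressed
    versus stable gene pairs. Ships a phased-diploid simulator that
    plants SNPs, structural variants, diverged and unique regions,
    hemizygous genes, telomere arrays, genetic-map markers and
    negative-binomial expression counts with a complete machine-readable
    truth set, so every stage of the pipeline can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
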