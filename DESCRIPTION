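Package: atacASB
Title: Allele-Specific Transcription Factor Binding from ATAC-Seq Footprints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects allele-specific transcription factor (TF) binding at
    heterozygous SNPs from ATAC-seq data. Tn5 cut sites are extracted with the
    standard +4/-5 offset, assigned to alleles at heterozygous sites inside
    open-chromatin peaks, and counted in footprint versus flanking regions
    around motif matches. A negative-binomial generalized linear model tests
    the allele-by-region interaction; allelic motif disruption is scored as
    the difference of position-specific scoring matrix (PSSM) scores between
    haplotypes. Candidate regulatory SNPs are linked to target genes via a
    promoter window and chromatin-interaction pairs, flagged for eQTL overlap,
    and checked for allele-specific expression with an exact binomial test.
    A simulator generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
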