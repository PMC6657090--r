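Package: delrecover
Title: Joint-Call Recovery and Curation of Intermediate-Sized Deletions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort-level curation of intermediate-sized deletions (30 bp to
    10 kb) called from short-read sequencing with soft-clip evidence.
    Implements breakpoint clustering of per-sample calls, joint-call recovery
    of single-orientation calls backed by both-orientation calls in other
    samples, a progressive filter cascade (size, region annotation, depth,
    soft-clip quality, similar-repeat breakpoints) with per-step accounting,
    Hardy-Weinberg exact testing and population filtering, reference-panel
    VCF export, deletion extraction from long-read CIGAR alignments with
    tolerance-based concordance evaluation, a cis-eQTL linear scan with
    per-window FDR control and genomic-inflation diagnostics, regulatory
    feature enrichment, and a deterministic synthetic-cohort generator with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'delrecover-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'merge-recover.R'
    'filters.R'
    'popgen.R'
    'eqtl.R'
    'io-formats.R'
    'longread.R'
    'synthgen.R'
    'pipeline.R'
    'utils.R'
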