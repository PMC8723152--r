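Package: igrsieve
Title: Enrichment of Bacterial Intergenic Regions for Structured
    Noncoding RNA Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts intergenic regions (IGRs) from annotated bacterial
    genomes, characterizes them by GC content and length, and trains a
    per-genome support-vector classifier with a radial basis-function
    kernel that enriches for IGRs resembling those harbouring known
    structured noncoding RNAs (riboswitch candidates in particular).
    Selected candidates are screened against protein-homology hit tables
    to remove unannotated coding stretches, deduplicated, and packaged
    into portable bundles for downstream covariance-model homology
    search. A synthetic-genome simulator with known ground truth
    supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    e1071,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Sequencing, Annotation, Classification, GenomeAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'igr-set.R'
    'genome-io.R'
    'igr-extraction.R'
    'svm-enrichment.R'
    'coding-filter.R'
    'motif-prep.R'
    'fixtures.R'
    'interface.R'
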