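Package: ecscall
Title: Error-Corrected Sequencing Consensus Calling and Rare Variant Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted error-corrected sequencing (ECS) of rare
    somatic variants, as used to detect clonal haematopoiesis well below the
    error rate of standard short-read sequencing. Implements unique molecular
    identifier (UMI) read-family consensus calling with configurable family
    size and per-position agreement thresholds, per-library pileups over a
    target space, a cross-individual position-specific binomial error model,
    the full rare-SNV filter chain with replicate concordance and clonal
    reporting, post-filters for externally generated candidate indels,
    Poisson-based droplet digital PCR quantification, and a seeded synthetic
    data generator (reads, pileups and droplets) with ground-truth ledgers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    SummarizedExperiment,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
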