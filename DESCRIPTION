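Package: methylscape
Title: Whole-Genome Bisulfite Methylome Analysis with Context-Aware
    Differential Methylation and Small-RNA Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    methylomes in plants. Quantifies per-cytosine methylation in the CG, CHG
    and CHH sequence contexts from Bismark-style cytosine count reports,
    estimates bisulfite conversion rates from an unmethylated spike-in
    genome, computes weighted and site-averaged methylation levels, metagene
    and meta-TE profiles, and expression-stratified methylation summaries.
    Calls differentially methylated cytosines and 1-kb differentially
    methylated regions between two samples with Fisher's exact test and
    Benjamini-Hochberg false discovery rate control, annotates regions to
    gene promoters, bodies and downstream flanks, and tests gene sets for
    term enrichment. Integrates small-RNA libraries: exact unique mapping,
    length distributions, positional methylated-cytosine association around
    24-nt siRNA loci, and genome-binned Spearman correlation between siRNA
    abundance and context-specific methylation. Ships a seeded synthetic
    data generator with planted differentially methylated regions and a
    ground-truth manifest so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
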