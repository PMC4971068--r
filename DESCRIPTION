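Package: filoplast
Title: Genome Plasticity Along Clonal Polyploid Bacterial Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing genome plasticity along segments of
    a clonal filament of large, highly polyploid sulfur bacteria. Compares
    near-identical per-segment genome assemblies by unique-k-mer anchoring and
    banded gap alignment to call SNPs and single-nucleotide indels, partitions
    them by coding status and reports densities per 100 kbp; calls
    intrasegmental sequence heterogeneity (ISH) events from read pileups with
    coverage and variant-frequency thresholds and quantifies their
    co-localization across segments; computes fragment-based two-way average
    nucleotide identity; and bundles a polyploid-filament simulator that emits
    reference, segment consensuses, annotations, pileups and ground-truth
    tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
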