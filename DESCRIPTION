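Package: tsvgraph
Title: Transcriptomic Structural Variant Detection from RNA-seq via Genome Segment Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects transcriptomic structural variants (TSVs) from paired-end
    RNA-seq alignments. The genome is partitioned into segments from discordant
    read pileups and zero-coverage gaps, a weighted genome segment graph is
    built over segment endpoints from concordant and discordant alignments, and
    segments are reordered and reoriented per connected component to maximize
    the total weight of compatible edges. Initially discordant edges that
    become compatible under the optimal arrangement are reported as TSV
    breakpoint pairs in BEDPE form. Includes an analytic simulator of
    rearranged genomes and paired-end RNA-seq alignments with derived
    ground-truth TSVs, plus window-based matching and breakpoint-partner
    entropy statistics for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    igraph,
    stats,
    utils,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
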