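Package: lincsel
Title: Splice-Related Purifying Selection on Long Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying splice-related purifying
    selection on spliced noncoding (and coding) genes from pairwise
    interspecies alignments. Annotates exonic splice enhancer (ESE) hexamers
    on gapped alignments, partitions genes into exon flanks, exon cores and
    intron cores, estimates region-stratified substitution rates with a
    lineage-heterogeneity-corrected distance, builds positional rate profiles
    with composition-matched nulls, tests stop-codon structure around the
    nonsense-mediated-decay shadow, relates chromatin peak density (CHD1,
    DNase hypersensitivity) to intron density and gene activity, and screens
    correlates of between-gene rate variation with rank partial correlations.
    Includes a fully seeded synthetic-data generator emulating gene models,
    diverged alignment pairs, expression tables and peak tracks, so every
    stage is testable without genome-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
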