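Package: chimscreen
Title: Cohort Screening for Sex-Biased Chimeric RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening fusion-caller output across an
    RNA-seq cohort for sex-biased chimeric RNAs, of the kind produced by
    transcriptional read-through between adjacent genes (cis-SAGe).
    Classifies fusion junctions against gene annotation (E/E to M/M by
    proximity to canonical exon boundaries), applies false-positive filters
    (caller score, local-alignment homology to annotated transcripts, M/M
    removal, cross-sample recurrence), aggregates detections per chimera and
    per individual, and tests each recurrent chimera for sex association with
    Pearson chi-squared and Fisher exact statistics, producing bubble-plot
    tables with a -log10(0.05) significance cutoff. Includes a seeded
    synthetic-cohort generator (annotation, transcript sequences, fusion
    calls, sample metadata and a ground-truth manifest) so every stage of the
    screen is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    Biostrings,
    ggplot2,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
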