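#' Classify a fusion junction against the annotation
#'
#' Each side of the junction is compared to the canonical exon boundaries
#' of its parental gene: the 5' breakpoint against donor ends of `gene5`,
#' the 3' breakpoint against acceptor starts of `gene3` (a splice junction
#' joins a donor to an acceptor). A side is `E` (edge of exon) when the
#' nearest boundary lies within `tolerance_bp` (inclusive), otherwise `M`
#' (middle of exon); the pair gives one of EE, EM, ME, MM.
#'
#' @param call A single fusion call (list or one-row data.frame with
#'   `gene5`, `gene3`, `pos5`, `pos3`).
#' @param annotation A [genome_annotation] containing both parental genes.
#' @param tolerance_bp Maximum absolute boundary offset still called `E`
#'   (default 2).
#' @return List with `value` (`"EE"`, `"EM"`, `"ME"` or `"MM"`), signed
#'   `offset5`/`offset3`, and the boundary query results `donor`/`acceptor`.
#' @export
classify_junction <- function(call, annotation, tolerance_bp = 2L) {
  g5 <- annotation$genes[[call$gene5]]
  g3 <- annotation$genes[[call$gene3]]
  for (miss in c(call$gene5, call$gene3)[c(is.null(g5), is.null(g3))])
    stop(structure(list(message = paste0("gene not in annotation: ", miss),
                        call = sys.call(-1), gene_id = miss),
                   class = c("chimscreen_unannotated", "error", "condition")))
  d <- boundary_offset(g5, call$pos5, "donor_end")
  a <- boundary_offset(g3, call$pos3, "acceptor_start")
  e5 <- abs(d$offset_bp) <= tolerance_bp
  e3 <- abs(a$offset_bp) <= tolerance_bp
  list(value = paste0(if (e5) "E" else "M", if (e3) "E" else "M"),
       offset5 = d$offset_bp, offset3 = a$offset_bp,
       donor = d, acceptor = a)
}

#' Chromosomal category of a fusion call
#'
#' Interchromosomal when the two breakpoints are on different chromosomes;
#' otherwise intrachromosomal, split at `cutoff_bp` (default 100 kb) on the
#' breakpoint distance into proximal (read-through range) and distal.
#'
#' @param call Fusion call with `chrom5`, `pos5`, `chrom3`, `pos3`.
#' @param cutoff_bp Proximal/distal distance cut in bp.
#' @return List with `value` and `distance_bp` (NA when interchromosomal).
#' @export
chromosomal_category <- function(call, cutoff_bp = 100000L) {
  if (call$chrom5 != call$chrom3)
    return(list(value = "interchromosomal", distance_bp = NA_integer_))
  d <- abs(as.integer(call$pos3) - as.integer(call$pos5))
  list(value = if (d <= cutoff_bp) "intrachromosomal_proximal"
       else "intrachromosomal_distal",
       distance_bp = d)
}

gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  c(min(ex[, 1]), max(ex[, 2]))
}

#' Annotate read-through (cis-SAGe) architecture
#'
#' Reports the exon ordinals at the junction, taken from the transcript
#' whose boundary lies nearest each breakpoint, and whether the fusion has
#' the geometry of read-through transcription between adjacent genes: same
#' strand, donor gene transcriptionally upstream of the acceptor gene, and
#' the junction joining the second-to-last exon of the upstream gene to
#' exon 2 of the downstream gene (`canonical_readthrough`). The isoform
#' label is `e<donor ordinal>e<acceptor ordinal>` counted from the
#' transcript start, e.g. `e24e2`. A breakpoint farther than `tolerance_bp`
#' from any boundary still gets the nearest exon's ordinals but is flagged
#' `non_edge`.
#'
#' @inheritParams classify_junction
#' @return List with `donor_exon_from_start`, `donor_exon_from_end`,
#'   `acceptor_exon_from_start`, `same_strand`, `donor_upstream`,
#'   `canonical_readthrough`, `isoform_label`, `non_edge`.
#' @export
annotate_architecture <- function(call, annotation, tolerance_bp = 2L) {
  cls <- classify_junction(call, annotation, tolerance_bp)
  g5 <- annotation$genes[[call$gene5]]
  g3 <- annotation$genes[[call$gene3]]
  same_strand <- g5$strand == g3$strand
  donor_upstream <- FALSE
  if (g5$chrom == g3$chrom) {
    s5 <- gene_span(g5); s3 <- gene_span(g3)
    donor_upstream <- if (g5$strand == "+") s5[2] < s3[1] else s5[1] > s3[2]
  }
  d <- cls$donor; a <- cls$acceptor
  canonical <- same_strand && donor_upstream &&
    d$exon_ordinal_from_end == 2L && a$exon_ordinal_from_start == 2L
  list(donor_exon_from_start = d$exon_ordinal_from_start,
       donor_exon_from_end = d$exon_ordinal_from_end,
       acceptor_exon_from_start = a$exon_ordinal_from_start,
       same_strand = same_strand,
       donor_upstream = donor_upstream,
       canonical_readthrough = canonical,
       isoform_label = sprintf("e%de%d", d$exon_ordinal_from_start,
                               a$exon_ordinal_from_start),
       non_edge = cls$value != "EE")
}

#' Annotate a table of fusion calls
#'
#' Vectorised driver: classifies every call (junction class, chromosomal
#' category, read-through architecture) against the annotation. Calls whose
#' parental genes are absent from the annotation are not dropped: they get
#' `unannotated = TRUE` and NA annotation columns.
#'
#' Identical (gene pair, breakpoint) junctions are classified once and the
#' result joined back, so cost scales with distinct junctions, not calls.
#'
#' @param calls Call `data.table` (see [call_table_columns()]).
#' @param annotation A [genome_annotation].
#' @param tolerance_bp E/M boundary tolerance in bp.
#' @param proximal_cutoff_bp Intrachromosomal proximal/distal cut in bp.
#' @return The call table with annotation columns appended.
#' @export
annotate_calls <- function(calls, annotation, tolerance_bp = 2L,
                           proximal_cutoff_bp = 100000L) {
  calls <- as.data.table(calls)
  key <- calls[, .(gene5, gene3, chrom5, pos5, chrom3, pos3)]
  uk <- unique(key)
  ann <- vector("list", nrow(uk))
  for (i in seq_len(nrow(uk))) {
    k <- as.list(uk[i])
    cat_ <- chromosomal_category(k, proximal_cutoff_bp)
    row <- data.table(junction_class = NA_character_,
                      offset5 = NA_integer_, offset3 = NA_integer_,
                      category = cat_$value, distance_bp = cat_$distance_bp,
                      donor_exon_from_start = NA_integer_,
                      donor_exon_from_end = NA_integer_,
                      acceptor_exon_from_start = NA_integer_,
                      isoform_label = NA_character_,
                      canonical_readthrough = NA,
                      unannotated = FALSE)
    hit <- tryCatch({
      cls <- classify_junction(k, annotation, tolerance_bp)
      arch <- annotate_architecture(k, annotation, tolerance_bp)
      row[, `:=`(junction_class = cls$value,
                 offset5 = as.integer(cls$offset5),
                 offset3 = as.integer(cls$offset3),
                 donor_exon_from_start = arch$donor_exon_from_start,
                 donor_exon_from_end = arch$donor_exon_from_end,
                 acceptor_exon_from_start = arch$acceptor_exon_from_start,
                 isoform_label = arch$isoform_label,
                 canonical_readthrough = arch$canonical_readthrough)]
      row
    }, chimscreen_unannotated = function(e) {
      row[, unannotated := TRUE]
      row
    })
    ann[[i]] <- cbind(uk[i], hit)
  }
  ann <- rbindlist(ann)
  out <- merge(calls, ann,
               by = c("gene5", "gene3", "chrom5", "pos5", "chrom3", "pos3"),
               sort = FALSE)
  setcolorder(out, intersect(call_table_columns(), names(out)))
  out[]
}

#' @importFrom data.table setcolorder
NULL
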