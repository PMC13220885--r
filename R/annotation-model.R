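#' Transcript model
#'
#' A transcript is an ordered list of exons given as 1-based inclusive
#' genomic intervals, sorted in transcript orientation (5' to 3' of the
#' mRNA): ascending genomic start on the plus strand, descending on the
#' minus strand.
#'
#' @param transcript_id Transcript identifier.
#' @param exons Two-column integer matrix (start, end), one row per exon,
#'   ordered 5' to 3' of the mRNA.
#' @param strand `"+"` or `"-"`; used only to validate exon ordering.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exons, strand = "+") {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons[, 1] > exons[, 2]))
    stop("transcript ", transcript_id, ": exon start > end")
  starts <- exons[, 1]
  if (nrow(exons) > 1L) {
    ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ok)
      stop("transcript ", transcript_id,
           ": exons not ordered 5'->3' for strand ", strand)
    # non-overlap check on genomically sorted intervals
    o <- order(exons[, 1])
    if (any(exons[o, 1][-1] <= exons[o, 2][-nrow(exons)]))
      stop("transcript ", transcript_id, ": overlapping exons")
  }
  structure(list(transcript_id = transcript_id, exons = exons),
            class = "transcript_model")
}

#' Gene model
#'
#' @param gene_id Gene identifier (unique within an annotation).
#' @param symbol Gene symbol; must be non-empty.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; shared by all transcripts of the gene.
#' @param transcripts List of [transcript_model] objects.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol, chrom, strand, transcripts) {
  if (!nzchar(symbol)) stop("gene ", gene_id, ": empty symbol")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": bad strand ", strand)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  transcripts <- transcripts[order(names(transcripts))]
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, transcripts = transcripts),
            class = "gene_model")
}

#' Genome annotation
#'
#' Container of [gene_model] objects keyed by gene id, with the set of
#' chromosome names seen.
#'
#' @param genes List of [gene_model] objects.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  genes <- genes[order(ids)]  # canonical order, so round-trips compare equal
  structure(list(genes = genes,
                 contig_names = unique(vapply(genes, `[[`, "", "chrom"))),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$genes), "genes on",
      length(x$contig_names), "contig(s)\n")
  invisible(x)
}

n_exons <- function(tx) nrow(tx$exons)

# Boundary coordinates of every exon of a transcript, in transcript
# orientation. A donor end is the 3' edge of an exon (where a splice donor
# sits), an acceptor start the 5' edge; on the minus strand the donor end
# is the genomically smaller coordinate.
boundary_positions <- function(tx, strand, side) {
  if (side == "donor_end") {
    if (strand == "+") tx$exons[, "end"] else tx$exons[, "start"]
  } else {
    if (strand == "+") tx$exons[, "start"] else tx$exons[, "end"]
  }
}

#' Nearest canonical exon boundary of a gene
#'
#' Scans every exon of every transcript of `gene` and returns the boundary
#' of the requested kind nearest to `genomic_pos`. The canonical boundary
#' set of a gene is the union over all of its annotated transcripts;
#' nearest wins, ties broken by lexicographically smallest transcript id,
#' then smallest exon ordinal.
#'
#' The offset is signed in transcript orientation: for a donor end, a
#' position inside the exon (5' of the boundary) gives a negative offset;
#' for an acceptor start, a position inside the exon (3' of the boundary)
#' gives a positive offset. An offset of 0 is an exact boundary hit.
#'
#' @param gene A [gene_model].
#' @param genomic_pos 1-based genomic coordinate on the gene's chromosome.
#' @param side `"donor_end"` or `"acceptor_start"`.
#' @return A list with `transcript_id`, `exon_ordinal_from_start`,
#'   `exon_ordinal_from_end` (both 1-based; their sum is exon count + 1)
#'   and `offset_bp`.
#' @export
boundary_offset <- function(gene, genomic_pos,
                            side = c("donor_end", "acceptor_start")) {
  side <- match.arg(side)
  if (length(gene$transcripts) == 0L)
    stop("gene ", gene$gene_id, " has no transcripts")
  sgn <- if (gene$strand == "+") 1L else -1L
  best <- NULL
  for (tid in sort(names(gene$transcripts))) {
    tx <- gene$transcripts[[tid]]
    bp <- boundary_positions(tx, gene$strand, side)
    off <- sgn * (genomic_pos - bp)
    k <- which.min(abs(off))  # first (smallest ordinal) among within-tx ties
    if (is.null(best) || abs(off[k]) < abs(best$offset_bp)) {
      best <- list(transcript_id = tid,
                   exon_ordinal_from_start = k,
                   exon_ordinal_from_end = n_exons(tx) - k + 1L,
                   offset_bp = off[k])
    }
  }
  best
}
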