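#' Read gene annotation from GTF
#'
#' Consumes exon features only. Attributes may use either the GTF
#' `key "value";` or the GFF3-like `key=value` syntax; `gene_id` and
#' `transcript_id` are required on every exon line, `gene_name` is used as
#' the gene symbol when present (falling back to the gene id). Transcripts
#' on the minus strand have their exons ordered 5' to 3' of the mRNA,
#' i.e. by descending genomic coordinate. Plain or gzip-compressed input.
#'
#' @param path Path to a GTF/GFF file.
#' @return A [genome_annotation].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (is_gz(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 9L)
      stop("GTF parse error at line ", lineno[i], ": expected 9 columns, got ",
           length(f))
    if (f[3] != "exon") next
    attrs <- f[9]
    gid <- gtf_attr(attrs, "gene_id")
    tid <- gtf_attr(attrs, "transcript_id")
    if (is.na(gid))
      stop("GTF parse error at line ", lineno[i], ": missing gene_id attribute")
    if (is.na(tid))
      stop("GTF parse error at line ", lineno[i],
           ": missing transcript_id attribute")
    recs[[i]] <- data.table(
      chrom = f[1], start = as.integer(f[4]), end = as.integer(f[5]),
      strand = f[7], gene_id = gid, transcript_id = tid,
      symbol = gtf_attr(attrs, "gene_name"))
  }
  ex <- rbindlist(recs)
  if (nrow(ex) == 0L) {
    warning("no exon features in ", path)
    return(genome_annotation(list()))
  }

  genes <- lapply(split(ex, by = "gene_id", sorted = TRUE), function(g) {
    strand <- g$strand[1]
    if (!all(g$strand == strand) || !all(g$chrom == g$chrom[1]))
      stop("gene ", g$gene_id[1], ": transcripts disagree on chrom/strand")
    txs <- lapply(split(g, by = "transcript_id", sorted = TRUE), function(t) {
      o <- order(t$start, decreasing = (strand == "-"))
      transcript_model(t$transcript_id[1],
                       cbind(t$start[o], t$end[o]), strand = strand)
    })
    sym <- g$symbol[!is.na(g$symbol)][1]
    gene_model(g$gene_id[1], if (is.na(sym)) g$gene_id[1] else sym,
               g$chrom[1], strand, unname(txs))
  })
  genome_annotation(unname(genes))
}

# extract one attribute from a GTF/GFF attribute string; NA when absent
gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs,
                  regexec(paste0('(?:^|;)\\s*', key, '(?:\\s+"([^"]*)"|=([^;]*))'),
                          attrs))[[1]]
  if (length(m) == 0L) return(NA_character_)
  val <- if (nzchar(m[2])) m[2] else m[3]
  if (nzchar(val)) val else NA_character_
}

#' Write a genome annotation back to GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `gene_name` attributes. Reading the file back with [read_gtf()] yields a
#' model identical to the one written.
#'
#' @param annotation A [genome_annotation].
#' @param path Output path (`.gz` for gzip).
#' @export
write_gtf <- function(annotation, path) {
  out <- character(0)
  for (g in annotation$genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons[order(tx$exons[, 1]), , drop = FALSE]
      out <- c(out, sprintf(
        '%s\tchimscreen\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
        g$chrom, ex[, 1], ex[, 2], g$strand, g$gene_id, tx$transcript_id,
        g$symbol))
    }
  }
  con <- if (is_gz(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' The first whitespace-delimited token of each header is taken as the
#' transcript id. Soft-masked (lowercase) bases are uppercased. Plain or
#' gzip-compressed input.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L ||
      (!is_gz(path) && length(readLines(path, n = 1L, warn = FALSE)) == 0L)) {
    warning("empty FASTA: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for ", paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(seqs, ids)
}

#' Write transcript sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_transcript_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = is_gz(path))
  invisible(path)
}
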