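#' Required columns of a cohort fusion-call table
#'
#' The cohort table is a concatenation of per-sample fusion-caller outputs
#' (EricScript-style) with an added `sample_id` column. `pos5` is the
#' 1-based coordinate of the last base of the 5' segment, `pos3` the first
#' base of the 3' segment; `score` is the caller's prediction score in
#' \[0,1\]; `junction_seq` spans the junction.
#'
#' @export
call_table_columns <- function() {
  c("sample_id", "gene5", "gene3", "chrom5", "pos5", "chrom3", "pos3",
    "strand5", "strand3", "score", "junction_seq", "reads_spanning")
}

#' Column mapping for native EricScript headers
#'
#' Maps this package's canonical call-table column names to the headers
#' EricScript itself emits, for use as the `col_map` argument of
#' [read_call_table()] when reading a concatenated EricScript table.
#'
#' @export
ericscript_col_map <- function() {
  c(gene5 = "GeneName1", gene3 = "GeneName2",
    chrom5 = "chr1", pos5 = "Breakpoint1", strand5 = "strand1",
    chrom3 = "chr2", pos3 = "Breakpoint2", strand3 = "strand2",
    score = "EricScore", junction_seq = "JunctionSequence",
    reads_spanning = "crossingreads")
}

#' Read a cohort fusion-call table
#'
#' Tab-separated with a header row; column order is free, columns are
#' matched by name. Rows violating the call invariants (score outside
#' \[0,1\], junction sequence shorter than 10 bases, identical 5'/3' genes,
#' unparseable coordinates) are rejected with row-numbered diagnostics and
#' returned in the `rejected` attribute; accepted + rejected = data rows.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's header names, e.g. [ericscript_col_map()].
#' @return A `data.table` of fusion calls with attribute `rejected`
#'   (a `data.table` of `row`, `reason`).
#' @export
read_call_table <- function(path, col_map = NULL) {
  dt <- fread_tsv(path, colClasses = "character")
  if (!is.null(col_map)) {
    present <- col_map[col_map %in% names(dt)]
    data.table::setnames(dt, unname(present), names(present))
  }
  missing <- setdiff(call_table_columns(), names(dt))
  if (length(missing))
    stop("call table ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  dt <- dt[, call_table_columns(), with = FALSE]

  n <- nrow(dt)
  pos5 <- suppressWarnings(as.integer(dt$pos5))
  pos3 <- suppressWarnings(as.integer(dt$pos3))
  score <- suppressWarnings(as.numeric(dt$score))
  reads <- suppressWarnings(as.integer(dt$reads_spanning))
  reason <- character(n)
  bad <- function(cond, why) {
    hit <- which(cond & !nzchar(reason))
    reason[hit] <<- why
  }
  bad(is.na(pos5) | is.na(pos3) | pos5 < 1L | pos3 < 1L,
      "unparseable junction coordinate")
  bad(is.na(score) | score < 0 | score > 1, "score outside [0,1]")
  bad(is.na(dt$junction_seq) | nchar(dt$junction_seq) < 10L,
      "junction sequence shorter than 10 bases")
  bad(dt$gene5 == dt$gene3, "identical 5' and 3' gene")
  bad(is.na(reads) | reads < 0L, "bad read-support count")

  keep <- !nzchar(reason)
  out <- dt[keep]
  data.table::set(out, j = "pos5", value = pos5[keep])
  data.table::set(out, j = "pos3", value = pos3[keep])
  data.table::set(out, j = "score", value = score[keep])
  data.table::set(out, j = "reads_spanning", value = reads[keep])
  out[, junction_seq := toupper(junction_seq)]
  rejected <- data.table(row = which(!keep), reason = reason[!keep])
  if (nrow(rejected))
    message(nrow(rejected), " call row(s) rejected (see attr 'rejected')")
  setattr(out, "rejected", rejected)
  out[]
}

#' @importFrom data.table setattr setnames
NULL

#' Write a cohort call table
#'
#' @param calls Call `data.table` with the columns of [call_table_columns()].
#' @param path Output TSV path (`.gz` supported).
#' @export
write_call_table <- function(calls, path) {
  fwrite(calls[, call_table_columns(), with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with header; requires `sample_id` and `sex`. Sex codes
#' `F`/`M`/`female`/`male` (any case) are normalised to `F`/`M`. Optional
#' columns `age`, `bmi`, `population` and `karyotype` are carried through;
#' karyotype is metadata only and never enters the statistics.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @return A `data.table` of sample metadata.
#' @export
read_metadata <- function(path) {
  dt <- fread_tsv(path)
  if (!all(c("sample_id", "sex") %in% names(dt)))
    stop("metadata ", path, " must have sample_id and sex columns")
  dt[, sample_id := as.character(sample_id)]
  if (anyDuplicated(dt$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(dt$sample_id[duplicated(dt$sample_id)]), collapse = ", "))
  sx <- toupper(as.character(dt$sex))
  sx[sx == "FEMALE"] <- "F"
  sx[sx == "MALE"] <- "M"
  badrow <- which(!sx %in% c("F", "M"))
  if (length(badrow))
    stop("unknown sex code at metadata row(s) ",
         paste(badrow, collapse = ", "), ": ",
         paste(unique(dt$sex[badrow]), collapse = ", "))
  dt[, sex := sx]
  for (opt in c("age", "bmi", "population", "karyotype"))
    if (!opt %in% names(dt)) dt[, (opt) := NA]
  dt[]
}

#' Write sample metadata
#' @param metadata Metadata `data.table`.
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  fwrite(metadata, path, sep = "\t")
  invisible(path)
}

#' Write screen results to a directory
#'
#' Writes `screen_results.tsv` (one row per surviving chimera with junction
#' class, chromosomal category, per-sex detection counts and association
#' statistics), `bubble.tsv`, `rejects.tsv` (per-call removal reasons) and
#' `summary.json` (stage accounting, parameters, seed, cutoff line). Row
#' order is deterministic: `chrom5`, `pos5`, then gene pair.
#'
#' @param result A screen result as returned by [run_pipeline()] /
#'   [sex_association_screen()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  res <- as.data.table(result$results)
  setorder(res, chrom5, pos5, gene5, gene3, pos3)
  paths <- c(results = file.path(out_dir, "screen_results.tsv"),
             bubble = file.path(out_dir, "bubble.tsv"),
             rejects = file.path(out_dir, "rejects.tsv"),
             summary = file.path(out_dir, "summary.json"))
  fwrite(res, paths["results"], sep = "\t")
  fwrite(as.data.table(result$bubble), paths["bubble"], sep = "\t")
  fwrite(as.data.table(result$rejects), paths["rejects"], sep = "\t")
  summary <- list(
    stage_counts = result$stage_counts,
    n_tested = result$n_tested,
    n_significant = result$n_significant,
    n_untestable = result$n_untestable %||% 0L,
    cutoff_line = result$cutoff_line,
    parameters = result$parameters,
    seed = result$seed,
    version = as.character(utils::packageVersion("chimscreen")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
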