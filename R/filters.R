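#' Screen filter configuration
#'
#' Defaults follow the screening procedure: caller score below 0.6 removed
#' ("less than", so exactly 0.6 is kept); junction probes with best
#' transcript identity strictly above 0.90 removed as homology artifacts;
#' M/M junctions removed; chimeras detected in fewer than 5 individuals
#' removed. Alignment scoring is +1/-1 with a -2 linear gap penalty.
#'
#' @param min_score Minimum caller score kept.
#' @param identity_threshold Probe identity strictly above which a call is
#'   removed as a transcript-homology artifact.
#' @param min_recurrence Minimum number of distinct individuals.
#' @param drop_MM Remove M/M-classified calls.
#' @param match_score,mismatch_penalty,gap_penalty Alignment parameters.
#' @param proximal_cutoff_bp Intrachromosomal proximal/distal cut (100 kb).
#' @param tolerance_bp E/M exon-boundary tolerance (2 bp).
#' @param merge_window_bp Breakpoint window within which calls of the same
#'   gene pair are merged into one chimera (0 = exact-coordinate identity).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_score = 0.6, identity_threshold = 0.90,
                          min_recurrence = 5L, drop_MM = TRUE,
                          match_score = 1L, mismatch_penalty = -1L,
                          gap_penalty = -2L, proximal_cutoff_bp = 100000L,
                          tolerance_bp = 2L, merge_window_bp = 0L) {
  stopifnot(min_score >= 0, min_score <= 1,
            identity_threshold > 0, identity_threshold <= 1,
            min_recurrence >= 1L, merge_window_bp >= 0L)
  structure(list(min_score = min_score,
                 identity_threshold = identity_threshold,
                 min_recurrence = as.integer(min_recurrence),
                 drop_MM = isTRUE(drop_MM),
                 match_score = as.integer(match_score),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_penalty = as.integer(gap_penalty),
                 proximal_cutoff_bp = as.integer(proximal_cutoff_bp),
                 tolerance_bp = as.integer(tolerance_bp),
                 merge_window_bp = as.integer(merge_window_bp)),
            class = "filter_config")
}

#' Caller-score filter
#'
#' Keeps calls with `score >= min_score` (scores strictly below the
#' threshold are putative false positives).
#'
#' @param calls Call `data.table`.
#' @param min_score Threshold in \[0,1\].
#' @return List of `kept` and `removed` call tables; `removed` carries a
#'   `reason` column.
#' @export
score_filter <- function(calls, min_score = 0.6) {
  calls <- as.data.table(calls)
  keep <- calls$score >= min_score
  removed <- calls[!keep]
  if (nrow(removed)) removed[, reason := sprintf("score %.3g < %.3g",
                                                 score, min_score)]
  else removed[, reason := character(0)]
  list(kept = calls[keep], removed = removed)
}

#' Transcript-homology filter
#'
#' Removes calls whose junction probe has a best local-alignment identity
#' strictly greater than `identity_threshold` to any annotated transcript
#' (such probes are read-through of a single transcript, not a chimera).
#' Identity is matches / probe length. Each distinct probe is aligned once.
#'
#' @param calls Call `data.table` with `junction_seq`.
#' @param transcripts Named character vector of transcript sequences.
#' @param identity_threshold Removal is strict: identity must exceed this.
#' @param match_score,mismatch_penalty,gap_penalty Alignment parameters.
#' @param cache Optional environment memoising probe -> best identity
#'   across calls (reused across screens of the same transcript set).
#' @return List of `kept` and `removed` (with `reason` naming the
#'   offending transcript and identity).
#' @export
homology_filter <- function(calls, transcripts, identity_threshold = 0.90,
                            match_score = 1L, mismatch_penalty = -1L,
                            gap_penalty = -2L, cache = NULL) {
  calls <- as.data.table(calls)
  if (length(transcripts) == 0L) {
    warning("empty transcript set: homology filter is a no-op")
    removed <- calls[0]
    removed[, reason := character(0)]
    return(list(kept = calls, removed = removed))
  }
  probes <- unique(calls$junction_seq)
  best <- vector("list", length(probes))
  names(best) <- probes
  for (p in probes) {
    if (!is.null(cache) && !is.null(cache[[p]])) { best[[p]] <- cache[[p]]; next }
    b <- best_transcript_identity(p, transcripts, match_score,
                                  mismatch_penalty, gap_penalty)
    best[[p]] <- b[c("identity", "target_id")]
    if (!is.null(cache)) cache[[p]] <- best[[p]]
  }
  ident <- vapply(best, `[[`, 0, "identity")[calls$junction_seq]
  tgt <- vapply(best, `[[`, "", "target_id")[calls$junction_seq]
  keep <- ident <= identity_threshold
  removed <- calls[!keep]
  if (nrow(removed))
    removed[, reason := sprintf("probe identity %.3f > %.2f to transcript %s",
                                ident[!keep], identity_threshold, tgt[!keep])]
  else removed[, reason := character(0)]
  list(kept = calls[keep], removed = removed)
}

#' Aggregate calls into per-chimera, per-individual detections
#'
#' A chimera is identified by (gene5, gene3, pos5, pos3); with
#' `merge_window_bp > 0`, calls of the same gene pair whose breakpoints lie
#' within the window are merged (single-linkage per side) and the smallest
#' coordinates represent the cluster. Detection is binary per sample:
#' repeat calls of one chimera in one sample count once. Sex counts come
#' from the metadata.
#'
#' @param calls Annotated call `data.table`.
#' @param metadata Sample metadata (must cover every `sample_id`).
#' @param merge_window_bp Breakpoint merge window (default 0, exact).
#' @return `data.table` with one row per chimera: key columns,
#'   representative annotation columns, `n_detected`,
#'   `n_female_detected`, `n_male_detected` and a `samples` list column.
#' @export
aggregate_calls <- function(calls, metadata, merge_window_bp = 0L) {
  calls <- as.data.table(calls)
  metadata <- as.data.table(metadata)
  missing <- setdiff(calls$sample_id, metadata$sample_id)
  if (length(missing))
    stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "))
  calls <- merge(calls, metadata[, .(sample_id, sex)], by = "sample_id",
                 sort = FALSE)
  if (merge_window_bp > 0L) {
    calls[, `:=`(pos5 = cluster_positions(pos5, merge_window_bp),
                 pos3 = cluster_positions(pos3, merge_window_bp)),
          by = .(gene5, gene3)]
  }
  ann_cols <- intersect(c("chrom5", "chrom3", "strand5", "strand3",
                          "junction_class", "offset5", "offset3", "category",
                          "distance_bp", "donor_exon_from_start",
                          "donor_exon_from_end", "acceptor_exon_from_start",
                          "isoform_label", "canonical_readthrough"),
                        names(calls))
  agg <- calls[, c(.(n_detected = uniqueN(sample_id),
                     n_female_detected = uniqueN(sample_id[sex == "F"]),
                     n_male_detected = uniqueN(sample_id[sex == "M"]),
                     samples = list(sort(unique(sample_id)))),
                   lapply(.SD, data.table::first)),
               by = .(gene5, gene3, pos5, pos3), .SDcols = ann_cols]
  setorder(agg, chrom5, pos5, gene5, gene3, pos3)
  agg[]
}

# map each position to the minimum of its single-linkage cluster
cluster_positions <- function(pos, window) {
  o <- order(pos)
  p <- pos[o]
  newclust <- c(TRUE, diff(p) > window)
  rep_pos <- p[newclust][cumsum(newclust)]
  out <- integer(length(pos))
  out[o] <- rep_pos
  out
}

#' Recurrence filter
#'
#' Keeps chimeras detected in at least `min_recurrence` distinct
#' individuals.
#'
#' @param aggregates Output of [aggregate_calls()].
#' @param min_recurrence Minimum individual count (kept when equal).
#' @return List of `kept` and `removed` aggregate tables.
#' @export
recurrence_filter <- function(aggregates, min_recurrence = 5L) {
  aggregates <- as.data.table(aggregates)
  keep <- aggregates$n_detected >= min_recurrence
  removed <- aggregates[!keep]
  if (nrow(removed))
    removed[, reason := sprintf("detected in %d < %d individuals",
                                n_detected, as.integer(min_recurrence))]
  else removed[, reason := character(0)]
  list(kept = aggregates[keep], removed = removed)
}

#' Run the full false-positive screen
#'
#' Applies, in order: caller-score filter, transcript-homology filter,
#' junction classification (unannotated gene pairs are routed out, not
#' silently dropped), M/M removal (optional), per-chimera aggregation and
#' the recurrence filter. Stage accounting satisfies
#' `input = kept + removed` at every stage; stages are counted in calls up
#' to aggregation, where the unit changes to chimeras (the accounting
#' records how many calls entered aggregation and how many chimeras came
#' out).
#'
#' @param calls Call `data.table` ([read_call_table()] or simulated).
#' @param metadata Sample metadata table.
#' @param annotation A [genome_annotation].
#' @param transcripts Named character vector of transcript sequences.
#' @param config A [filter_config()].
#' @param align_cache Optional environment passed to [homology_filter()].
#' @return List with `aggregates` (surviving chimeras), `stage_counts`,
#'   `rejects` (per-call/per-chimera removal records) and `annotated`
#'   (annotated calls that reached aggregation).
#' @export
run_screen <- function(calls, metadata, annotation, transcripts,
                       config = filter_config(), align_cache = NULL) {
  calls <- as.data.table(calls)
  stages <- list(); rejects <- list()
  note <- function(stage, unit, input, kept, removed_dt, keep_cols) {
    stages[[length(stages) + 1L]] <<- data.table(
      stage = stage, unit = unit, input_n = input, kept_n = kept,
      removed_n = input - kept)
    if (nrow(removed_dt))
      rejects[[length(rejects) + 1L]] <<-
        cbind(removed_dt[, keep_cols, with = FALSE],
              data.table(stage = stage, reason = removed_dt$reason))
  }
  id_cols <- c("sample_id", "gene5", "gene3", "pos5", "pos3")

  s <- score_filter(calls, config$min_score)
  note("score", "calls", nrow(calls), nrow(s$kept), s$removed, id_cols)

  h <- homology_filter(s$kept, transcripts, config$identity_threshold,
                       config$match_score, config$mismatch_penalty,
                       config$gap_penalty, cache = align_cache)
  note("homology", "calls", nrow(s$kept), nrow(h$kept), h$removed, id_cols)

  ann <- annotate_calls(h$kept, annotation, config$tolerance_bp,
                        config$proximal_cutoff_bp)
  unann <- ann[unannotated == TRUE]
  if (nrow(unann)) unann[, reason := "parental gene absent from annotation"]
  else unann[, reason := character(0)]
  ann <- ann[unannotated == FALSE]
  note("classify", "calls", nrow(h$kept), nrow(ann), unann, id_cols)

  if (config$drop_MM) {
    mm <- ann[junction_class == "MM"]
    if (nrow(mm)) mm[, reason := "M/M junction (both breakpoints mid-exon)"]
    else mm[, reason := character(0)]
    ann <- ann[junction_class != "MM"]
    note("drop_mm", "calls", nrow(ann) + nrow(mm), nrow(ann), mm, id_cols)
  }

  agg <- aggregate_calls(ann, metadata, config$merge_window_bp)
  stages[[length(stages) + 1L]] <- data.table(
    stage = "aggregate", unit = "chimeras", input_n = nrow(agg),
    kept_n = nrow(agg), removed_n = 0L)
  attr(stages[[length(stages)]], "calls_in") <- nrow(ann)

  r <- recurrence_filter(agg, config$min_recurrence)
  rem <- r$removed
  note("recurrence", "chimeras", nrow(agg), nrow(r$kept),
       if (nrow(rem)) rem else rem[, reason := character(0)][0],
       setdiff(id_cols, "sample_id"))

  stage_counts <- rbindlist(stages)
  stage_counts[stage == "aggregate", calls_in := nrow(ann)]
  stage_counts[is.na(calls_in), calls_in := NA_integer_]
  list(aggregates = r$kept, stage_counts = stage_counts,
       rejects = if (length(rejects)) rbindlist(rejects, fill = TRUE)
                 else data.table(sample_id = character(0),
                                 gene5 = character(0), gene3 = character(0),
                                 pos5 = integer(0), pos3 = integer(0),
                                 stage = character(0), reason = character(0)),
       annotated = ann)
}

#' @importFrom data.table uniqueN
NULL
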