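#' Local alignment of a junction probe against a transcript
#'
#' Smith–Waterman local alignment with match/mismatch scoring and a linear
#' gap penalty (each gapped base costs `gap`). `N` bases never match: they
#' score as mismatches and are excluded from the match count. Among
#' co-optimal alignments the one with the most matches is reported, then
#' the one starting earliest in the target.
#'
#' Identity is defined as matches divided by the probe length (not by
#' aligned columns), so a probe whose best alignment covers only one arm of
#' a chimeric junction scores about 0.5 — this is what lets the homology
#' filter separate genuine chimeras from probes that are near-copies of a
#' single annotated transcript.
#'
#' @param probe Junction probe sequence (non-empty, A/C/G/T/N).
#' @param target Transcript sequence.
#' @param match,mismatch,gap Alignment scores (defaults +1, -1, -2).
#' @return List with `score`, `matches`, `aligned_columns`, `identity`,
#'   and the 1-based alignment span (`probe_start/end`, `target_start/end`).
#' @export
local_align <- function(probe, target, match = 1L, mismatch = -1L, gap = -2L) {
  if (!nzchar(probe)) stop("empty probe")
  r <- sw_align_cpp(toupper(probe), toupper(target),
                    as.integer(match), as.integer(mismatch), as.integer(gap))
  r$identity <- r$matches / nchar(probe)
  r
}

#' Exhaustive reference local aligner (validation only)
#'
#' Enumerates every monotone matching between subsequences of probe and
#' target and scores each directly, applying the same tie-breaks as
#' [local_align()]. Exponential: restricted to probes of at most 10 and
#' targets of at most 16 bases. Used as an independent oracle in tests.
#'
#' @inheritParams local_align
#' @return List with `score`, `matches`, `aligned_columns`, `identity`,
#'   `target_start`.
#' @export
local_align_exhaustive <- function(probe, target, match = 1L, mismatch = -1L,
                                   gap = -2L) {
  r <- sw_enumerate_cpp(toupper(probe), toupper(target),
                        as.integer(match), as.integer(mismatch),
                        as.integer(gap))
  r$identity <- r$matches / nchar(probe)
  r
}

#' Best identity of a probe over a transcript set
#'
#' @param probe Junction probe sequence.
#' @param transcripts Named character vector of transcript sequences.
#' @param match,mismatch,gap Alignment scores.
#' @return List with `identity`, `target_id` of the best-identity
#'   transcript, and the winning `alignment`.
#' @export
best_transcript_identity <- function(probe, transcripts, match = 1L,
                                     mismatch = -1L, gap = -2L) {
  best <- list(identity = -1, target_id = NA_character_, alignment = NULL)
  for (tid in names(transcripts)) {
    al <- local_align(probe, transcripts[[tid]], match, mismatch, gap)
    if (al$identity > best$identity)
      best <- list(identity = al$identity, target_id = tid, alignment = al)
  }
  best
}
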