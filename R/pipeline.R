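pipeline_defaults <- function() {
  c(list(calls = NULL, metadata = NULL, gtf = NULL, fasta = NULL,
         out_dir = NULL, alpha = 0.05, plot = FALSE, seed = NULL),
    unclass(filter_config()))
}

#' Read a pipeline configuration file
#'
#' Flat key-value YAML. Precedence: explicit `overrides` beat file values,
#' which beat built-in defaults (the [filter_config()] defaults plus
#' `alpha = 0.05`).
#'
#' @param path YAML config path, or NULL for defaults only.
#' @param overrides Named list of values taking precedence over the file.
#' @return Named list of pipeline settings.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stage_stop("config", "no such config file: ", path)
    fromfile <- yaml::read_yaml(path)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown))
      stage_stop("config", "unknown config key(s): ",
                 paste(unknown, collapse = ", "))
    cfg[names(fromfile)] <- fromfile
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stage_stop("config", "unknown override key(s): ",
               paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

config_to_filter <- function(cfg) {
  do.call(filter_config, cfg[intersect(names(cfg), names(unclass(filter_config())))])
}

#' Screen a cohort and test sex association
#'
#' Composition of [run_screen()], [sex_association()] and [bubble_table()]
#' into one result object: the false-positive filters, per-chimera
#' aggregation, per-chimera Pearson chi-squared (with Fisher exact and
#' BH-adjusted companions) and the bubble-plot table with its
#' -log10(alpha) cutoff line.
#'
#' @param calls Call table.
#' @param metadata Sample metadata (defines the cohort sex totals).
#' @param annotation A [genome_annotation].
#' @param transcripts Named character vector of transcript sequences.
#' @param config A [filter_config()].
#' @param alpha Significance level for the cutoff line.
#' @param align_cache Optional alignment memoisation environment.
#' @return List with `results` (per-chimera table), `bubble`,
#'   `stage_counts`, `rejects`, `n_tested`, `n_significant`,
#'   `n_untestable`, `cutoff_line`, `n_female`, `n_male`.
#' @export
sex_association_screen <- function(calls, metadata, annotation, transcripts,
                                   config = filter_config(), alpha = 0.05,
                                   align_cache = NULL) {
  metadata <- as.data.table(metadata)
  n_f <- sum(metadata$sex == "F"); n_m <- sum(metadata$sex == "M")
  scr <- run_screen(calls, metadata, annotation, transcripts, config,
                    align_cache = align_cache)
  res <- sex_association(scr$aggregates, n_f, n_m, alpha)
  res[, samples := NULL]
  bub <- bubble_table(res, alpha)
  list(results = res, bubble = bub$rows, stage_counts = scr$stage_counts,
       rejects = scr$rejects, n_tested = sum(!res$untestable),
       n_significant = sum(res$significant, na.rm = TRUE),
       n_untestable = bub$n_untestable, cutoff_line = bub$cutoff_line,
       n_female = n_f, n_male = n_m)
}

#' Run the pipeline from files
#'
#' Reads the call table, metadata, annotation and transcript FASTA named
#' in the configuration, runs the screen and sex-association testing, and
#' writes `screen_results.tsv`, `bubble.tsv`, `rejects.tsv` and
#' `summary.json` (plus `bubble.png` when `plot: true`) to `out_dir`.
#' Any validation error aborts before partial outputs are written, with a
#' diagnostic naming the failing stage.
#'
#' @param config_path Optional YAML config file.
#' @param overrides Named list of settings taking precedence over the file
#'   (e.g. `list(min_recurrence = 1)`).
#' @return The summary report (stage counts, n_tested, n_significant,
#'   parameter echo, seed, cutoff line), invisibly.
#' @export
run_pipeline <- function(config_path = NULL, overrides = list()) {
  cfg <- read_pipeline_config(config_path, overrides)
  for (key in c("calls", "metadata", "gtf", "fasta")) {
    if (is.null(cfg[[key]]))
      stage_stop("config", "missing required path: ", key)
    if (!file.exists(cfg[[key]]))
      stage_stop("config", "file not found for '", key, "': ", cfg[[key]])
  }
  if (is.null(cfg$out_dir)) stage_stop("config", "missing out_dir")

  calls <- tryCatch(read_call_table(cfg$calls),
                    error = function(e) stage_stop("read_calls", conditionMessage(e)))
  metadata <- tryCatch(read_metadata(cfg$metadata),
                       error = function(e) stage_stop("read_metadata", conditionMessage(e)))
  annotation <- tryCatch(read_gtf(cfg$gtf),
                         error = function(e) stage_stop("read_gtf", conditionMessage(e)))
  transcripts <- tryCatch(read_transcript_fasta(cfg$fasta),
                          error = function(e) stage_stop("read_fasta", conditionMessage(e)))

  fc <- config_to_filter(cfg)
  out <- sex_association_screen(calls, metadata, annotation, transcripts,
                                fc, alpha = cfg$alpha)
  out$parameters <- cfg[setdiff(names(cfg), c("seed", "out_dir"))]
  out$seed <- cfg$seed
  paths <- write_results(out, cfg$out_dir)
  if (isTRUE(cfg$plot))
    plot_bubble(list(rows = out$bubble, cutoff_line = out$cutoff_line),
                file.path(cfg$out_dir, "bubble.png"))
  message(sprintf("screen: %d chimeras tested, %d significant (cutoff %.2f)",
                  out$n_tested, out$n_significant, out$cutoff_line))
  invisible(out)
}

#' Recompute the run summary from written results
#'
#' Re-derives `n_tested`, `n_significant` and the cutoff line from an
#' existing `screen_results.tsv`, so a report can be regenerated without
#' rerunning the screen; idempotent with respect to the original run.
#'
#' @param results_path Path to `screen_results.tsv`.
#' @param alpha Significance level.
#' @return List with `n_tested`, `n_significant`, `n_untestable`,
#'   `cutoff_line`.
#' @export
pipeline_report <- function(results_path, alpha = 0.05) {
  res <- fread(results_path, sep = "\t")
  cutoff <- -log10(alpha)
  tested <- res[untestable == FALSE]
  list(n_tested = nrow(tested),
       n_significant = sum(tested$neg_log10_p >= cutoff, na.rm = TRUE),
       n_untestable = sum(res$untestable),
       cutoff_line = cutoff)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: builds a [simulation_config()] (or takes one),
#' simulates the cohort and writes the pipeline input files plus the
#' truth manifest to `dir`.
#'
#' @param dir Output directory.
#' @param config A [simulation_config()], or NULL to build one from `...`.
#' @param ... Passed to [simulation_config()] when `config` is NULL.
#' @return The simulated cohort (invisibly), with `paths` attribute.
#' @export
pipeline_simulate <- function(dir, config = NULL, ...) {
  cfg <- config %||% simulation_config(...)
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, dir)
  attr(sim, "paths") <- paths
  invisible(sim)
}

#' Annotate a call table against an annotation (standalone)
#'
#' Runs junction classification, chromosomal category and read-through
#' architecture only — no filtering — and returns the annotated table.
#'
#' @param calls_path Call table TSV.
#' @param gtf_path Annotation GTF.
#' @param tolerance_bp,proximal_cutoff_bp See [annotate_calls()].
#' @return Annotated call `data.table`.
#' @export
pipeline_annotate <- function(calls_path, gtf_path, tolerance_bp = 2L,
                              proximal_cutoff_bp = 100000L) {
  annotate_calls(read_call_table(calls_path), read_gtf(gtf_path),
                 tolerance_bp, proximal_cutoff_bp)
}
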