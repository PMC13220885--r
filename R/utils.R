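#' @useDynLib chimscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom data.table data.table as.data.table setDT setkey := rbindlist fread fwrite setorder
#' @importFrom stats rbinom runif rpois pchisq dhyper p.adjust setNames
#' @importFrom utils head tail
NULL

# Deterministic per-component sub-seeds. Components draw from a fixed
# registry so adding a new component never perturbs the draws of an
# existing one. The mix is a Knuth-style multiplicative hash kept below
# .Machine$integer.max.
.component_registry <- c(
  annotation = 1L, sequences = 2L, samples = 3L, background = 4L,
  planted = 5L, low_score = 6L, mm_artifact = 7L, homology_artifact = 8L,
  scores = 9L, reads = 10L
)

substream_seed <- function(seed, component) {
  idx <- .component_registry[[component]]
  if (is.null(idx)) stop("unknown seed component: ", component)
  as.integer((as.double(seed) * 48271 + idx * 69621) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a prefix naming the pipeline stage, so orchestration errors
# carry a single diagnostic naming where they arose
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

is_gz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

# fread with transparent gzip support (no optional-package dependency)
fread_tsv <- function(path, ...) {
  if (is_gz(path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    fread(text = readLines(con, warn = FALSE), sep = "\t", header = TRUE, ...)
  } else {
    fread(path, sep = "\t", header = TRUE, ...)
  }
}

# data.table / ggplot2 non-standard-evaluation column names
utils::globalVariables(c(
  "gene5", "gene3", "chrom5", "chrom3", "pos5", "pos3", "sample_id", "sex",
  "score", "reason", "junction_seq", "junction_class", "unannotated",
  "n_detected", "neg_log10_p", "pct_female", "total_detected", "untestable",
  "p", "p_adjusted", "significant", "calls_in", "x", "y", "size", "color",
  "role", "stage", "kept_n", "input_n", "removed_n", "penetrance_female",
  "penetrance_male", "n_female_detected", "n_male_detected", "label", "."
))
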