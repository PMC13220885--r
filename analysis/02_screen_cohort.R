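#!/usr/bin/env Rscript
# Run the false-positive screen and sex-association testing on the cohort
# produced by 01_simulate_cohort.R: caller-score filter (>= 0.6), junction
# homology filter (> 90% identity to an annotated transcript removed),
# junction classification with M/M removal, per-individual aggregation,
# recurrence filter (>= 5 individuals), then per-chimera Pearson
# chi-squared with the -log10(0.05) = 1.3 bubble-plot cutoff.

suppressPackageStartupMessages(library(chimscreen))

SEED <- 1L
cohort <- "results/cohort"
stopifnot(dir.exists(cohort))  # run 01_simulate_cohort.R first

out <- run_pipeline(overrides = list(
  calls = file.path(cohort, "calls.tsv"),
  metadata = file.path(cohort, "metadata.tsv"),
  gtf = file.path(cohort, "annotation.gtf"),
  fasta = file.path(cohort, "transcripts.fa"),
  out_dir = "results/screen",
  seed = SEED, plot = TRUE))

cat("\nstage accounting:\n")
print(out$stage_counts)
cat(sprintf("\n%d chimeras tested, %d significant at the 1.3 cutoff\n",
            out$n_tested, out$n_significant))
res <- out$results[order(out$results$p), ]
cat("\nmost sex-biased chimeras:\n")
print(res[1:5, c("gene5", "gene3", "junction_class", "category",
                 "isoform_label", "n_female_detected", "n_male_detected",
                 "chi2", "p", "neg_log10_p", "pct_female", "significant")])
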