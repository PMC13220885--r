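---
title: "Screening cohorts for sex-biased chimeric RNAs: methods and design"
author: "chimscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohorts for sex-biased chimeric RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimscreen)
library(data.table)
```

## The problem

Chimeric RNAs join sequence from two parental genes without any DNA
rearrangement. The class this package targets arises from transcriptional
read-through between adjacent same-strand genes (cis-splicing between
adjacent genes, cis-SAGe): the polymerase reads past the upstream gene's
termination site into its downstream neighbour and splicing joins an exon
of the upstream gene to an exon (typically exon 2) of the downstream gene.
Fusion callers run on bulk RNA-seq emit many such candidates per sample,
most of them artifacts. Given per-sample fusion-call tables across a
cohort of female and male donors, the screen asks: which chimeras are
real, recurrent, and detected at significantly different rates in the two
sexes? The motivating discovery was a blood-restricted chimera between two
neighbouring X-chromosome genes, detected in 24 of 157 women and 0 of 268
men, whose junction joins the third-from-last exon of the upstream gene
(exon 24 of a 26-exon transcript) to exon 2 of the downstream gene — the
"e24e2" isoform in the e{donor}e{acceptor} naming used here.

## Pipeline stages

`run_screen()` applies, in order:

1. **Caller-score filter.** Calls with a prediction score below 0.6 are
   removed; a score of exactly 0.6 is kept (the rule removes scores
   *less than* the threshold).
2. **Transcript-homology filter.** The junction probe is locally aligned
   against every annotated transcript; a call is removed when its best
   identity is *strictly greater* than 0.90. Identity is defined as
   matches divided by **probe length**, not by aligned columns, so a
   probe that is a near-copy of one transcript scores near 1 while a
   genuine chimeric probe — half of which comes from each parent — tops
   out near 0.5 against any single transcript. This is a deliberate,
   documented divergence from BLAT's exact identity formula: at junction
   scale it behaves like a coverage-weighted identity and is what makes
   the filter discriminative.
3. **Junction classification.** Each side of the junction is compared to
   the canonical exon boundaries of its parental gene, defined as the
   union of boundaries over all annotated transcripts of that gene. A side
   is `E` (edge) when the nearest boundary is within 2 bp **inclusive**
   (the plain reading of "within 2 bp"), else `M` (middle); the pair gives
   E/E, E/M, M/E or M/M. The 5' side is compared only against donor ends
   (the transcript-orientation 3' edge of an exon) and the 3' side only
   against acceptor starts, because a splice junction joins a donor to an
   acceptor. This donor/acceptor restriction is this package's choice: a
   looser rule comparing against any boundary would differ only for
   junctions that sit at the "wrong" kind of boundary, which the
   classification keeps visible through the signed offsets it records.
   On the minus strand the donor end is the genomically smaller exon
   coordinate; offsets are signed in transcript orientation (negative =
   inside the exon for a donor side).
4. **M/M removal.** Both-sides-mid-exon calls are a recognised
   false-positive class and are dropped (configurable).
5. **Aggregation.** Detection is binary per (sample, chimera): multiple
   calls of one chimera in one sample count once, because the statistics
   count individuals. A chimera is keyed by (5' gene, 3' gene, 5'
   breakpoint, 3' breakpoint) exactly; an optional `merge_window_bp`
   single-linkage merge is available for callers with jittery breakpoints,
   default off because the emulated caller reports consistent junctions.
6. **Recurrence filter.** Chimeras detected in at least 5 distinct
   individuals are kept. The source material states both "more than five"
   and "≥ 5"; the default follows ≥ 5, which defines the recurrent set the
   screen was built around, and the comparator is configurable.

Chromosomal category is annotated alongside: interchromosomal, or
intrachromosomal split at 100 kb of breakpoint distance into proximal
(read-through range) and distal. Distance uses breakpoints, not gene
spans, because breakpoints are what call tables carry.

### Stage accounting

Every stage satisfies input = kept + removed, and consecutive stages
chain. Aggregation changes the counting unit from calls to chimeras, so
the conservation law cannot hold across that boundary in a single unit;
the stage table therefore carries a `unit` column, chaining is asserted
within each unit, and the aggregation row records both the calls that
entered and the chimeras that came out. Removed calls are logged to
`rejects.tsv` with the removing stage and reason, so accepted + rejected
always reconstructs the input.

## Association testing

For each surviving chimera the 2x2 table (detected/not x female/male) is
tested with Pearson's chi-squared in the closed form

$$\chi^2 = \frac{N(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}, \qquad df = 1,$$

with **no Yates continuity correction** — Pearson's test is what the
screen names, and zero-cell tables such as (24, 133, 0, 268) remain
testable under it. A table with a zero *column* margin (detected by
nobody or everybody) has nothing to test and is flagged untestable rather
than given a number; in practice the recurrence filter keeps such tables
out. The Fisher exact two-sided p (hypergeometric point-probability sum)
is reported alongside as the safer reference for heavily unbalanced
tables, and Benjamini–Hochberg adjusted values are reported in an extra
column. The headline `significant` flag uses the **raw** Pearson p at
$-\log_{10} p \ge -\log_{10} 0.05 = 1.3$, exactly as the bubble-plot
cutoff line is drawn; that choice mirrors the original display and is why
about 5% of truly sex-independent chimeras cross the line (the benchmark
script measures this rate). The bubble table orders chimeras by the
genomic position of the 5' breakpoint — the source display leaves the
x-axis unspecified, and genomic rank is reproducible and interpretable.

A note on the validation-scale table (474 of 525 females vs 173 of 727
males): Pearson's closed form gives $\chi^2 \approx 540$, corresponding to
a p-value far below the 2.7e-53 printed in the source material, which is
not reproducible from the printed counts under any standard 2x2 test we
know; the package reports both Pearson and Fisher values and treats
neither as an external reference for that table.

## The local aligner

The homology filter needs a local aligner with controlled semantics:
Smith–Waterman with match +1, mismatch -1 and a linear gap penalty of -2
per gapped base. `N` never matches — it scores as a mismatch and is
excluded from the match count. Among co-optimal alignments the one with
the most matches is chosen, then the one starting earliest in the target;
the match-count tie-break matters because identity is defined through
matches. Cells whose running score is exactly zero keep their non-empty
alignment rather than resetting, since a zero-score prefix can add
matches to a co-optimal alignment; only negative scores reset. This is
what makes the cell-local tie-breaks globally exact (an exchange argument
on prefixes), and it is verified against `local_align_exhaustive()`, an
independent reference that enumerates every monotone matching between
subsequences and scores it directly — exponential, and therefore
restricted to probes of at most 10 and targets of at most 16 bases. Full
dynamic programming over all transcripts is acceptable at this scale; no
seeding heuristic is used, and repeated probes are aligned once.

## The synthetic cohort

`simulate_cohort()` generates everything the screen consumes — GTF,
transcript FASTA, call table, metadata, truth manifest — from one seed.
What it emulates is the *detection-level* statistical structure of the
screen's input:

- **Geometry.** Adjacent same-strand gene pairs on one chromosome with a
  configurable intergenic spacing (default 9124 bp, the read-through-range
  distance of the motivating chimera, well inside the 100-kb proximal
  cut); one transcript per gene, 6 exons of 60 bp by default — big enough
  that 25-bp junction arms always fit inside a transcript prefix/suffix,
  small enough that full Smith–Waterman across all transcripts stays
  fast.
- **Detection.** Each chimera is detected in each sample as an
  independent Bernoulli draw with a sex-specific penetrance. The planted
  chimera defaults to 0.15 in females and 0 in males (157 x 0.15 ≈ 24
  expected female detections, matching the discovery pattern of 24/157 vs
  0/268); background chimeras use 0.10 in both sexes — the source
  material gives no background detection rate, so this was fixed once as
  a realistic mid-range value and is exposed in the configuration.
- **Artifacts.** Low-score artifacts draw caller scores uniformly below
  0.6 (genuine calls draw in [0.6, 1]); M/M artifacts place both
  breakpoints 5 bp inside exons (beyond the 2-bp tolerance); homology
  artifacts copy their probe from a single transcript with exactly one
  mutated base (identity ≥ 0.98 > 0.90). Each class is constructed to be
  caught by exactly one stage, which is what lets the recovery benchmark
  assert *which* stage removed each artifact.
- **Junctions.** Genuine probes are 25 bases from each parent transcript
  around true exon boundaries; the planted chimera joins the
  third-from-last donor exon to acceptor exon 2, mirroring the e24e2
  architecture.
- **Reproducibility.** One master seed feeds fixed per-component
  substreams (annotation, detection per chimera class, scores, read
  counts), so adding an artifact class never perturbs the background
  draws — important when comparing configurations.

What it does **not** emulate, and what passing tests therefore do not
show about real data: expression levels and coverage-dependent detection
sensitivity (detection is binary), correlated detection between chimeras
or between samples, sequencing error in junction probes, annotation
incompleteness (every simulated gene is annotated), caller-specific score
distributions, and population structure or covariates (age, BMI). A
clean separation of artifact classes is also idealised; real artifacts
can violate several filters at once.

## Problem sizes and numerical choices

The test suite exercises the screen at the discovery geometry (157/268)
with 50 background chimeras and 5 artifacts per class: 200 seeded
replicates for planted-chimera recovery (flagged significant in at least
95% of replicates; observed 100%) and artifact-stage attribution, and
2000 simulated sex-independent chimeras for null calibration of the
Pearson test (fraction with p < 0.05 within 3 Monte-Carlo standard errors
of 0.05). These sizes give tight Monte-Carlo error at interactive
runtimes. Ties in boundary matching are broken by lexicographically
smallest transcript id, then smallest exon ordinal, making every
annotation query deterministic; output tables are sorted by (chromosome,
5' breakpoint, gene pair) so repeated runs are byte-identical, with the
run timestamp isolated to a single summary field.

## Configuration and orchestration

`run_pipeline()` reads a flat YAML configuration naming the four input
files and any filter settings; explicit overrides beat file values, which
beat built-in defaults, and unknown keys are rejected. The numbered
scripts under `analysis/` are thin drivers over the package: simulate the
cohort, screen it, compute the worked association statistics, and run the
recovery benchmark, writing their tables under `results/`.

## Known limitations

- The homology filter scores whole-probe identity; it does not require
  the high-identity alignment to span the junction point itself (whether
  the original BLAT filter did is unstated). The alignment span is
  logged, so a span-based variant could be added without changing the
  interface.
- Exact-coordinate chimera identity undercounts recurrence for callers
  with breakpoint jitter; `merge_window_bp` exists but single-linkage
  merging can chain distinct junctions at large windows.
- The Pearson test is asymptotic; for chimeras near the recurrence
  threshold in small cohorts the Fisher column is the better guide.
- Covariate-adjusted association (age, BMI, population) is out of scope;
  karyotype is carried through the metadata but never modelled.
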