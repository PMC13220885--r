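#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate the discovery cohort geometry: 157 female and 268 male
#' individuals, background chimeras detected sex-independently in about 10%
#' of samples, one planted female-specific chimera with penetrance 0.15 in
#' females and 0 in males (the detection pattern of a blood-restricted
#' female-specific read-through chimera), and three artifact classes that
#' the screen must remove: low caller score, M/M junctions, and junction
#' probes nearly identical to one annotated transcript. Genuine calls draw
#' scores in \[0.6, 1\], low-score artifacts in \[0, 0.6).
#'
#' @param n_female,n_male Cohort sizes by sex.
#' @param n_background_chimeras Sex-independent background chimeras.
#' @param background_detect_prob Per-sample detection probability of each
#'   background chimera (both sexes).
#' @param planted List of planted chimeras, each a list with `label`,
#'   `penetrance_female`, `penetrance_male`.
#' @param n_low_score_artifacts,n_mm_artifacts,n_homology_artifacts
#'   Artifact counts per class.
#' @param artifact_detect_prob Per-sample detection probability of each
#'   artifact (both sexes).
#' @param score_real_range Caller-score interval for genuine calls, within
#'   \[0.6, 1\].
#' @param score_artifact_range Score interval for low-score artifacts,
#'   within \[0, 0.6).
#' @param junction_arm_length Bases contributed by each parent transcript
#'   to a junction probe (default 25 per side).
#' @param gene_pair_spacing_bp Intergenic distance of simulated adjacent
#'   gene pairs (default 9124 bp, read-through range, well under the
#'   100-kb proximal cut).
#' @param exons_per_gene,exon_length_bp,intron_length_bp Simulated gene
#'   geometry.
#' @param seed Master seed; every random draw flows from it through fixed
#'   per-component substreams.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_female = 157L, n_male = 268L,
                              n_background_chimeras = 50L,
                              background_detect_prob = 0.10,
                              planted = list(list(label = "planted_1",
                                                  penetrance_female = 0.15,
                                                  penetrance_male = 0)),
                              n_low_score_artifacts = 5L,
                              n_mm_artifacts = 5L,
                              n_homology_artifacts = 5L,
                              artifact_detect_prob = 0.10,
                              score_real_range = c(0.6, 1),
                              score_artifact_range = c(0, 0.6),
                              junction_arm_length = 25L,
                              gene_pair_spacing_bp = 9124L,
                              exons_per_gene = 6L, exon_length_bp = 60L,
                              intron_length_bp = 200L, seed = 1L) {
  stopifnot(n_female >= 1L, n_male >= 1L,
            background_detect_prob >= 0, background_detect_prob <= 1,
            artifact_detect_prob >= 0, artifact_detect_prob <= 1,
            exons_per_gene >= 3L, junction_arm_length >= 5L)
  if (score_real_range[1] < 0.6 || score_real_range[2] > 1)
    stop("score_real_range must lie within [0.6, 1]")
  if (score_artifact_range[1] < 0 || score_artifact_range[2] > 0.6)
    stop("score_artifact_range must lie within [0, 0.6)")
  for (p in planted)
    stopifnot(p$penetrance_female >= 0, p$penetrance_female <= 1,
              p$penetrance_male >= 0, p$penetrance_male <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Cohort presets
#'
#' `"gtex-blood"`: 157 females, 268 males (the discovery cohort geometry).
#' `"clinical-blood"`: 525 females, 727 males (the validation cohort
#' geometry).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [simulation_config()].
#' @export
cohort_preset <- function(name = c("gtex-blood", "clinical-blood"), ...) {
  name <- match.arg(name)
  sizes <- switch(name,
                  "gtex-blood" = c(157L, 268L),
                  "clinical-blood" = c(525L, 727L))
  simulation_config(n_female = sizes[1], n_male = sizes[2], ...)
}

#' Generate a synthetic annotation and transcript set
#'
#' Lays out `n_gene_pairs` adjacent same-strand gene pairs on one synthetic
#' chromosome. Within a pair, the downstream gene starts
#' `gene_pair_spacing_bp` after the upstream gene ends (read-through
#' geometry); pairs are separated by 1 Mb. Each gene has one transcript of
#' `exons_per_gene` exons; transcript sequences are uniform random A/C/G/T.
#' Deterministic given `seed`.
#'
#' @param n_gene_pairs Number of gene pairs (>= 1).
#' @param exons_per_gene Exons per gene (>= 3).
#' @param exon_length_bp,intron_length_bp Exon/intron sizes in bp.
#' @param gene_pair_spacing_bp Intergenic distance within a pair (>= 1).
#' @param chrom Chromosome name.
#' @param seed Seed for the transcript sequences.
#' @return List with `annotation` (a [genome_annotation]) and
#'   `transcripts` (named character vector). Gene ids are `G<i>U`
#'   (upstream) and `G<i>D` (downstream) for pair `i`; transcript ids
#'   append `.1`.
#' @export
generate_annotation <- function(n_gene_pairs, exons_per_gene = 6L,
                                exon_length_bp = 60L, intron_length_bp = 200L,
                                gene_pair_spacing_bp = 9124L,
                                chrom = "chrS1", seed = 1L) {
  stopifnot(n_gene_pairs >= 1L, exons_per_gene >= 3L)
  if (gene_pair_spacing_bp < 1L) stop("gene_pair_spacing_bp must be >= 1")
  set.seed(substream_seed(seed, "sequences"))
  gene_len <- exons_per_gene * exon_length_bp +
    (exons_per_gene - 1L) * intron_length_bp
  genes <- list(); seqs <- character(0)
  pos <- 1L
  for (i in seq_len(n_gene_pairs)) {
    for (part in c("U", "D")) {
      gid <- sprintf("G%d%s", i, part)
      starts <- pos + (seq_len(exons_per_gene) - 1L) *
        (exon_length_bp + intron_length_bp)
      exons <- cbind(starts, starts + exon_length_bp - 1L)
      tx <- transcript_model(paste0(gid, ".1"), exons, strand = "+")
      genes[[gid]] <- gene_model(gid, gid, chrom, "+", list(tx))
      seqs[[paste0(gid, ".1")]] <- paste(
        sample(c("A", "C", "G", "T"), exons_per_gene * exon_length_bp,
               replace = TRUE), collapse = "")
      pos <- pos + gene_len +
        if (part == "U") as.integer(gene_pair_spacing_bp) else 1000000L
    }
  }
  list(annotation = genome_annotation(unname(genes)), transcripts = seqs)
}

# transcript-coordinate prefix sums of exon lengths
exon_cumlen <- function(tx) cumsum(tx$exons[, 2] - tx$exons[, 1] + 1L)

# junction probe: `arm` bases of the donor transcript ending at transcript
# position tpos5, then `arm` bases of the acceptor transcript starting at
# transcript position tpos3
junction_probe <- function(seq5, tpos5, seq3, tpos3, arm) {
  paste0(substr(seq5, tpos5 - arm + 1L, tpos5),
         substr(seq3, tpos3, tpos3 + arm - 1L))
}

# mutate one random base of a probe to a different nucleotide
mutate_one <- function(probe) {
  i <- sample.int(nchar(probe), 1L)
  old <- substr(probe, i, i)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(probe, 1L, i - 1L), new, substr(probe, i + 1L, nchar(probe)))
}

#' Simulate a cohort of fusion calls with planted ground truth
#'
#' Assigns one simulated gene pair to each chimera (planted sex-specific
#' chimeras first, then background, then the three artifact classes) and
#' draws, per sample and chimera, an independent Bernoulli detection with
#' the sex-appropriate penetrance. Genuine junctions sit exactly on exon
#' boundaries (donor: third-from-last exon for planted, a random internal
#' exon for background; acceptor: exon 2) with probes made of one arm from
#' each parent transcript, so their best single-transcript identity is
#' about 0.5. M/M artifacts have both breakpoints 5 bp inside exons;
#' homology artifacts copy their probe from a single transcript with one
#' mutated base (identity > 0.9); low-score artifacts draw caller scores
#' below 0.6. All randomness flows from `config$seed` through fixed
#' per-component substreams, so adding an artifact class does not perturb
#' background draws.
#'
#' @param config A [simulation_config()].
#' @param annotation,transcripts Output of [generate_annotation()]; when
#'   NULL, generated from the config (pair geometry and seed).
#' @return List with `calls` (cohort call table), `metadata` (sample
#'   table), `truth` (manifest: one row per chimera with role, per-sex
#'   penetrance and emitted samples) and the `annotation`/`transcripts`
#'   used.
#' @export
simulate_cohort <- function(config, annotation = NULL, transcripts = NULL) {
  cfg <- config
  n_planted <- length(cfg$planted)
  n_chim <- n_planted + cfg$n_background_chimeras +
    cfg$n_low_score_artifacts + cfg$n_mm_artifacts + cfg$n_homology_artifacts
  if (is.null(annotation) || is.null(transcripts)) {
    ga <- generate_annotation(
      n_gene_pairs = n_chim, exons_per_gene = cfg$exons_per_gene,
      exon_length_bp = cfg$exon_length_bp,
      intron_length_bp = cfg$intron_length_bp,
      gene_pair_spacing_bp = cfg$gene_pair_spacing_bp, seed = cfg$seed)
    annotation <- ga$annotation; transcripts <- ga$transcripts
  }
  n_pairs <- length(annotation$genes) %/% 2L
  if (n_pairs < n_chim)
    stop("annotation has ", n_pairs, " gene pairs but ", n_chim,
         " chimeras are configured")

  metadata <- data.table(
    sample_id = c(sprintf("F%04d", seq_len(cfg$n_female)),
                  sprintf("M%04d", seq_len(cfg$n_male))),
    sex = rep(c("F", "M"), c(cfg$n_female, cfg$n_male)),
    age = NA_integer_, bmi = NA_real_, population = NA_character_,
    karyotype = NA_character_)

  roles <- rep(c("planted_sex_specific", "background", "low_score_artifact",
                 "mm_artifact", "homology_artifact"),
               c(n_planted, cfg$n_background_chimeras,
                 cfg$n_low_score_artifacts, cfg$n_mm_artifacts,
                 cfg$n_homology_artifacts))

  # per-chimera junction design, deterministic given seed
  set.seed(substream_seed(cfg$seed, "planted"))
  arm <- cfg$junction_arm_length
  nex <- cfg$exons_per_gene
  chim <- vector("list", n_chim)
  for (k in seq_len(n_chim)) {
    gu <- annotation$genes[[sprintf("G%dU", k)]]
    gd <- annotation$genes[[sprintf("G%dD", k)]]
    txu <- gu$transcripts[[1]]; txd <- gd$transcripts[[1]]
    squ <- transcripts[[txu$transcript_id]]
    sqd <- transcripts[[txd$transcript_id]]
    cum_u <- exon_cumlen(txu); cum_d <- exon_cumlen(txd)
    role <- roles[k]
    donor_exon <- switch(role,
      planted_sex_specific = nex - 2L,             # third from last
      sample(2:(nex - 1L), 1L))                    # internal exon
    acceptor_exon <- 2L
    if (role == "mm_artifact") {
      inset <- 5L
      pos5 <- txu$exons[donor_exon, 2] - inset
      pos3 <- txd$exons[acceptor_exon, 1] + inset
      probe <- junction_probe(squ, cum_u[donor_exon] - inset,
                              sqd, cum_d[acceptor_exon - 1L] + 1L + inset, arm)
    } else {
      pos5 <- txu$exons[donor_exon, 2]
      pos3 <- txd$exons[acceptor_exon, 1]
      probe <- junction_probe(squ, cum_u[donor_exon],
                              sqd, cum_d[acceptor_exon - 1L] + 1L, arm)
    }
    if (role == "homology_artifact")
      probe <- mutate_one(substr(squ, 1L, 2L * arm))
    pf <- pm <- NA_real_
    label <- sprintf("chim_%03d", k)
    if (role == "planted_sex_specific") {
      pl <- cfg$planted[[k]]
      pf <- pl$penetrance_female; pm <- pl$penetrance_male
      label <- pl$label
    } else if (role == "background") {
      pf <- pm <- cfg$background_detect_prob
    } else {
      pf <- pm <- cfg$artifact_detect_prob
    }
    chim[[k]] <- data.table(
      label = label, role = role, gene5 = gu$gene_id, gene3 = gd$gene_id,
      chrom5 = gu$chrom, chrom3 = gd$chrom, pos5 = as.integer(pos5),
      pos3 = as.integer(pos3), strand5 = gu$strand, strand3 = gd$strand,
      junction_seq = probe, penetrance_female = pf, penetrance_male = pm)
  }
  chim <- rbindlist(chim)

  # detection draws: one substream per chimera class
  detect <- matrix(FALSE, nrow(metadata), n_chim)
  is_f <- metadata$sex == "F"
  for (cls in unique(roles)) {
    set.seed(substream_seed(cfg$seed, switch(cls,
      planted_sex_specific = "planted", background = "background",
      low_score_artifact = "low_score", mm_artifact = "mm_artifact",
      homology_artifact = "homology_artifact")))
    for (k in which(roles == cls)) {
      pr <- ifelse(is_f, chim$penetrance_female[k], chim$penetrance_male[k])
      detect[, k] <- runif(nrow(metadata)) < pr
    }
  }

  set.seed(substream_seed(cfg$seed, "scores"))
  emit <- which(detect, arr.ind = TRUE)
  emit <- emit[order(emit[, 2], emit[, 1]), , drop = FALSE]
  n_call <- nrow(emit)
  low <- chim$role[emit[, 2]] == "low_score_artifact"
  scr <- numeric(n_call)
  scr[!low] <- runif(sum(!low), cfg$score_real_range[1],
                     cfg$score_real_range[2])
  scr[low] <- runif(sum(low), cfg$score_artifact_range[1],
                    min(cfg$score_artifact_range[2], 0.6 - 1e-9))
  set.seed(substream_seed(cfg$seed, "reads"))
  reads <- rpois(n_call, 8L) + 2L

  calls <- cbind(
    data.table(sample_id = metadata$sample_id[emit[, 1]]),
    chim[emit[, 2],
         .(gene5, gene3, chrom5, pos5, chrom3, pos3, strand5, strand3)],
    data.table(score = round(scr, 6), junction_seq = chim$junction_seq[emit[, 2]],
               reads_spanning = reads))
  setorder(calls, sample_id, gene5, gene3)

  truth <- chim[, .(label, role, gene5, gene3, pos5, pos3,
                    penetrance_female, penetrance_male)]
  truth[, samples := lapply(seq_len(n_chim), function(k)
    sort(metadata$sample_id[detect[, k]]))]
  truth[, n_emitted := vapply(samples, length, 0L)]
  check_truth_consistency(calls, truth)
  list(calls = calls, metadata = metadata, truth = truth,
       annotation = annotation, transcripts = transcripts)
}

#' Assert call-table / truth-manifest consistency
#'
#' Every (chimera, sample) emission in the manifest must appear exactly
#' once in the call table, and vice versa.
#'
#' @param calls Simulated call table.
#' @param truth Truth manifest from [simulate_cohort()].
#' @return TRUE invisibly; stops on inconsistency.
#' @export
check_truth_consistency <- function(calls, truth) {
  from_truth <- rbindlist(lapply(seq_len(nrow(truth)), function(k)
    data.table(gene5 = truth$gene5[k], gene3 = truth$gene3[k],
               sample_id = truth$samples[[k]])))
  from_calls <- as.data.table(calls)[, .(gene5, gene3, sample_id)]
  setkey(from_truth, gene5, gene3, sample_id)
  setkey(from_calls, gene5, gene3, sample_id)
  if (!identical(unname(as.list(from_truth)), unname(as.list(from_calls))))
    stop("truth manifest and call table disagree on emitted detections")
  invisible(TRUE)
}

#' Write a simulated cohort to disk
#'
#' Emits the exact formats the pipeline consumes: `annotation.gtf`,
#' `transcripts.fa`, `calls.tsv`, `metadata.tsv`, plus `truth.tsv` (with
#' emitted samples as a comma-separated list).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             fasta = file.path(dir, "transcripts.fa"),
             calls = file.path(dir, "calls.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_gtf(sim$annotation, paths["gtf"])
  write_transcript_fasta(sim$transcripts, paths["fasta"])
  write_call_table(sim$calls, paths["calls"])
  write_metadata(sim$metadata, paths["metadata"])
  tr <- as.data.table(sim$truth)
  tr[, samples := vapply(samples, paste, "", collapse = ",")]
  fwrite(tr, paths["truth"], sep = "\t")
  invisible(paths)
}
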