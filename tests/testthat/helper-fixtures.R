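# Hand-built two-gene annotation: one plus-strand gene with three exons and
# one minus-strand gene with two exons, with known boundary coordinates.
tiny_annotation <- function() {
  ga <- gene_model(
    "GENEA", "GENEA", "chrT", "+",
    list(transcript_model("TA.1",
                          rbind(c(101L, 200L), c(301L, 400L), c(501L, 600L)),
                          strand = "+")))
  gb <- gene_model(
    "GENEB", "GENEB", "chrT", "-",
    list(transcript_model("TB.1",
                          rbind(c(1201L, 1300L), c(1001L, 1100L)),
                          strand = "-")))
  genome_annotation(list(ga, gb))
}

tiny_gtf_text <- function() {
  c('chrT\ttest\texon\t101\t200\t.\t+\t.\tgene_id "GENEA"; transcript_id "TA.1"; gene_name "GENEA";',
    'chrT\ttest\texon\t301\t400\t.\t+\t.\tgene_id "GENEA"; transcript_id "TA.1"; gene_name "GENEA";',
    'chrT\ttest\texon\t501\t600\t.\t+\t.\tgene_id "GENEA"; transcript_id "TA.1"; gene_name "GENEA";',
    'chrT\ttest\texon\t1001\t1100\t.\t-\t.\tgene_id "GENEB"; transcript_id "TB.1"; gene_name "GENEB";',
    'chrT\ttest\texon\t1201\t1300\t.\t-\t.\tgene_id "GENEB"; transcript_id "TB.1"; gene_name "GENEB";')
}

# one fusion call row with overridable fields
make_call <- function(sample_id = "S1", gene5 = "GENEA", gene3 = "GENEB",
                      chrom5 = "chrT", pos5 = 400L, chrom3 = "chrT",
                      pos3 = 1300L, strand5 = "+", strand3 = "-",
                      score = 0.9, junction_seq = strrep("ACGT", 10),
                      reads_spanning = 5L) {
  data.table::data.table(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
                         chrom5 = chrom5, pos5 = as.integer(pos5),
                         chrom3 = chrom3, pos3 = as.integer(pos3),
                         strand5 = strand5, strand3 = strand3, score = score,
                         junction_seq = junction_seq,
                         reads_spanning = as.integer(reads_spanning))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Ten-call screen fixture over four simulated gene pairs:
#   2 low-score calls, 1 transcript-homology artifact, 1 M/M call, and
#   6 genuine calls forming two chimeras detected in 4 and 2 individuals.
screen_fixture <- function() {
  ga <- generate_annotation(4, exons_per_gene = 5, seed = 42)
  ann <- ga$annotation; txs <- ga$transcripts
  jseq <- function(pair, inset = 0L) {
    gu <- ann$genes[[sprintf("G%dU", pair)]]
    gd <- ann$genes[[sprintf("G%dD", pair)]]
    txu <- gu$transcripts[[1]]; txd <- gd$transcripts[[1]]
    cum <- cumsum(txu$exons[, 2] - txu$exons[, 1] + 1L)
    su <- txs[[txu$transcript_id]]; sd <- txs[[txd$transcript_id]]
    list(pos5 = txu$exons[4, 2] - inset, pos3 = txd$exons[2, 1] + inset,
         seq = paste0(substr(su, cum[4] - inset - 24L, cum[4] - inset),
                      substr(sd, 61L + inset, 61L + inset + 24L)))
  }
  j1 <- jseq(1); j4 <- jseq(4); j3 <- jseq(3, inset = 5L)
  homology_probe <- substr(txs[["G2U.1"]], 1, 50)
  calls <- data.table::rbindlist(list(
    make_call("S1", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.20, junction_seq = j1$seq),
    make_call("S2", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.59, junction_seq = j1$seq),
    make_call("S1", "G2U", "G2D", "chrS1", 1L, "chrS1", 2L,
              strand3 = "+", score = 0.90, junction_seq = homology_probe),
    make_call("S2", "G3U", "G3D", "chrS1", j3$pos5, "chrS1", j3$pos3,
              strand3 = "+", score = 0.90, junction_seq = j3$seq),
    make_call("S3", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.80, junction_seq = j1$seq),
    make_call("S4", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.85, junction_seq = j1$seq),
    make_call("S5", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.95, junction_seq = j1$seq),
    make_call("S6", "G1U", "G1D", "chrS1", j1$pos5, "chrS1", j1$pos3,
              strand3 = "+", score = 0.70, junction_seq = j1$seq),
    make_call("S1", "G4U", "G4D", "chrS1", j4$pos5, "chrS1", j4$pos3,
              strand3 = "+", score = 0.75, junction_seq = j4$seq),
    make_call("S2", "G4U", "G4D", "chrS1", j4$pos5, "chrS1", j4$pos3,
              strand3 = "+", score = 0.99, junction_seq = j4$seq)))
  metadata <- data.table::data.table(
    sample_id = paste0("S", 1:6),
    sex = c("F", "F", "F", "M", "M", "M"))
  list(calls = calls, metadata = metadata, annotation = ann,
       transcripts = txs)
}

# small cohort configuration that keeps unit tests fast
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_female = 25L, n_male = 35L, n_background_chimeras = 4L,
               n_low_score_artifacts = 2L, n_mm_artifacts = 2L,
               n_homology_artifacts = 2L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# data.frame comparison form: drop data.table attributes and rejection log
plain_df <- function(d) {
  d <- as.data.frame(d)
  attr(d, "rejected") <- NULL
  rownames(d) <- NULL
  d
}
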