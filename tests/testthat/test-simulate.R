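test_that("generated annotation is deterministic and correctly sized", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    ga <- generate_annotation(3, exons_per_gene = 5, seed = 1)
    write_gtf(ga$annotation, file.path(d, "a.gtf"))
    write_transcript_fasta(ga$transcripts, file.path(d, "t.fa"))
  }
  expect_identical(readLines(file.path(d1, "a.gtf")),
                   readLines(file.path(d2, "a.gtf")))
  expect_identical(readLines(file.path(d1, "t.fa")),
                   readLines(file.path(d2, "t.fa")))
  ga <- generate_annotation(3, exons_per_gene = 5, seed = 1)
  expect_length(ga$annotation$genes, 6L)
  expect_identical(sum(vapply(ga$annotation$genes, function(g)
    nrow(g$transcripts[[1]]$exons), 0L)), 30L)
  expect_error(generate_annotation(2, gene_pair_spacing_bp = 0), ">= 1")
})

test_that("pair spacing reproduces read-through proximal geometry", {
  ga <- generate_annotation(2, gene_pair_spacing_bp = 9124L, seed = 3)
  gu <- ga$annotation$genes[["G1U"]]; gd <- ga$annotation$genes[["G1D"]]
  txu <- gu$transcripts[[1]]; txd <- gd$transcripts[[1]]
  call <- list(chrom5 = gu$chrom, pos5 = txu$exons[nrow(txu$exons), 2],
               chrom3 = gd$chrom, pos3 = txd$exons[1, 1])
  cat_ <- chromosomal_category(call)
  expect_identical(cat_$value, "intrachromosomal_proximal")
  # intergenic spacing is exactly as configured
  expect_identical(cat_$distance_bp, 9124L + 1L)
})

test_that("simulated cohorts are deterministic and truth-consistent", {
  s1 <- simulate_cohort(small_sim_config(seed = 4))
  s2 <- simulate_cohort(small_sim_config(seed = 4))
  expect_equal(as.data.frame(s1$calls), as.data.frame(s2$calls))
  expect_true(check_truth_consistency(s1$calls, s1$truth))
  s3 <- simulate_cohort(small_sim_config(seed = 5))
  expect_false(identical(as.data.frame(s1$calls), as.data.frame(s3$calls)))
  # metadata geometry
  expect_identical(sum(s1$metadata$sex == "F"), 25L)
  expect_identical(sum(s1$metadata$sex == "M"), 35L)
  # roles partition all chimeras
  expect_identical(as.integer(table(s1$truth$role)[c(
    "planted_sex_specific", "background", "low_score_artifact",
    "mm_artifact", "homology_artifact")]), c(1L, 4L, 2L, 2L, 2L))
})

test_that("planted detections follow the per-sex penetrance", {
  counts_f <- counts_m <- integer(0)
  for (seed in 1:8) {
    cfg <- simulation_config(n_female = 157, n_male = 268,
                             n_background_chimeras = 2,
                             n_low_score_artifacts = 0, n_mm_artifacts = 0,
                             n_homology_artifacts = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    planted <- sim$truth[role == "planted_sex_specific"]
    sx <- substr(planted$samples[[1]], 1, 1)
    counts_f <- c(counts_f, sum(sx == "F"))
    counts_m <- c(counts_m, sum(sx == "M"))
  }
  # Binomial(157, 0.15): mean 23.55, sd 4.47; all draws within 3 sd
  expect_true(all(abs(counts_f - 23.55) <= 3 * 4.474))
  expect_identical(counts_m, rep(0L, 8))
})

test_that("sex-independent chimeras show no systematic female excess", {
  pct <- numeric(0)
  for (seed in 1:10) {
    cfg <- simulation_config(n_female = 80, n_male = 120,
                             n_background_chimeras = 10,
                             background_detect_prob = 0.2,
                             planted = list(), n_low_score_artifacts = 0,
                             n_mm_artifacts = 0, n_homology_artifacts = 0,
                             seed = seed)
    sim <- simulate_cohort(cfg)
    sx <- substr(unlist(sim$truth$samples), 1, 1)
    pct <- c(pct, 100 * mean(sx == "F"))
  }
  # expectation is 100 * 80/200 = 40%
  expect_lt(abs(mean(pct) - 40), 3)
})

test_that("simulated junctions have the structure each filter expects", {
  sim <- simulate_cohort(small_sim_config(seed = 6))
  ann <- annotate_calls(unique(sim$calls, by = c("gene5", "gene3")),
                        sim$annotation)
  ann <- merge(ann, sim$truth[, .(gene5, gene3, role)],
               by = c("gene5", "gene3"))
  expect_true(all(ann[role %in% c("planted_sex_specific",
                                  "background")]$junction_class == "EE"))
  expect_true(all(ann[role == "mm_artifact"]$junction_class == "MM"))
  # genuine probes have ~0.5 identity, homology artifacts > 0.9
  for (i in seq_len(nrow(ann))) {
    b <- best_transcript_identity(ann$junction_seq[i], sim$transcripts)
    if (ann$role[i] == "homology_artifact") expect_gt(b$identity, 0.9)
    else expect_lt(b$identity, 0.9)
  }
  # low-score artifacts draw below 0.6, all other calls at or above
  calls <- merge(sim$calls, sim$truth[, .(gene5, gene3, role)],
                 by = c("gene5", "gene3"))
  expect_true(all(calls[role == "low_score_artifact"]$score < 0.6))
  expect_true(all(calls[role != "low_score_artifact"]$score >= 0.6))
})

test_that("adding artifact classes does not perturb background draws", {
  base <- simulate_cohort(small_sim_config(seed = 8))
  more <- simulate_cohort(small_sim_config(seed = 8,
                                           n_homology_artifacts = 4L))
  b1 <- base$truth[role == "background"]
  b2 <- more$truth[role == "background"]
  expect_identical(b1$samples, b2$samples)
})

test_that("cohort presets carry the study geometries", {
  g <- cohort_preset("gtex-blood")
  expect_identical(c(g$n_female, g$n_male), c(157L, 268L))
  cl <- cohort_preset("clinical-blood")
  expect_identical(c(cl$n_female, cl$n_male), c(525L, 727L))
})

test_that("written cohorts are consumable by the readers", {
  d <- withr::local_tempdir()
  sim <- simulate_cohort(small_sim_config(seed = 9))
  paths <- write_cohort(sim, d)
  expect_equal(plain_df(read_call_table(paths[["calls"]])),
               plain_df(sim$calls))
  expect_identical(nrow(read_metadata(paths[["metadata"]])), 60L)
  expect_equal(read_gtf(paths[["gtf"]]), sim$annotation)
  expect_identical(read_transcript_fasta(paths[["fasta"]]), sim$transcripts)
})
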