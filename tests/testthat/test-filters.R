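test_that("score filter keeps exactly-threshold calls and accounts stages", {
  calls <- data.table::rbindlist(list(
    make_call("S1", score = 0.59), make_call("S2", score = 0.60),
    make_call("S3", score = 1.0)))
  f <- score_filter(calls, 0.6)
  expect_identical(f$kept$sample_id, c("S2", "S3"))
  expect_match(f$removed$reason, "score")
  # all high scores: identity mapping
  f2 <- score_filter(calls[score == 1.0], 0.6)
  expect_identical(nrow(f2$removed), 0L)
  # empty input
  f3 <- score_filter(calls[0], 0.6)
  expect_identical(nrow(f3$kept) + nrow(f3$removed), 0L)
})

test_that("homology filter removes >90% identity, keeps exactly 90%", {
  tx <- c(t1 = random_seq(100))
  # 19/20 identical probe: identity 0.95 -> removed
  probe95 <- paste0(substr(tx[["t1"]], 11, 29), "A")
  if (substr(tx[["t1"]], 30, 30) == "A")
    probe95 <- paste0(substr(tx[["t1"]], 11, 29), "C")
  # exactly 18/20 = 0.90 -> kept (strictly-greater removal)
  base <- substr(tx[["t1"]], 41, 60)
  probe90 <- paste0("NN", substr(base, 3, 20))
  calls <- data.table::rbindlist(list(
    make_call("S1", junction_seq = probe95),
    make_call("S2", junction_seq = probe90),
    make_call("S3", junction_seq = paste0(substr(tx[["t1"]], 1, 10),
                                          strrep("N", 10)))))
  f <- homology_filter(calls, tx, 0.90)
  expect_identical(f$removed$sample_id, "S1")
  expect_match(f$removed$reason, "t1")
  expect_setequal(f$kept$sample_id, c("S2", "S3"))
  expect_warning(f0 <- homology_filter(calls, character(0), 0.9), "no-op")
  expect_identical(nrow(f0$kept), 3L)
})

test_that("homology filter is monotone in the identity threshold", {
  set.seed(5)
  tx <- c(t1 = random_seq(200), t2 = random_seq(200))
  calls <- data.table::rbindlist(lapply(1:15, function(i) {
    src <- if (i %% 3 == 0) random_seq(30) else {
      s <- substr(tx[[sample(2, 1)]], i, i + 29)
      if (i %% 2 == 0) paste0(substr(s, 1, 15), random_seq(15)) else s
    }
    make_call(paste0("S", i), junction_seq = src)
  }))
  kept_prev <- character(0)
  for (th in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    kept <- homology_filter(calls, tx, th)$kept$sample_id
    expect_true(all(kept_prev %in% kept))
    kept_prev <- kept
  }
})

test_that("aggregation counts individuals once and splits on coordinates", {
  md <- data.table::data.table(sample_id = paste0("S", 1:6),
                               sex = c("F", "F", "F", "M", "M", "M"))
  calls <- data.table::rbindlist(list(
    make_call("S1"), make_call("S1"),               # same chimera twice in S1
    make_call("S2"), make_call("S3"),
    make_call("S4"), make_call("S5"),
    make_call("S6", pos3 = 1301L)))                 # 1 bp off: distinct
  agg <- aggregate_calls(calls, md)
  expect_identical(nrow(agg), 2L)
  main <- agg[pos3 == 1300L]
  expect_identical(main$n_detected, 5L)
  expect_identical(main$n_female_detected, 3L)
  expect_identical(main$n_male_detected, 2L)
  expect_identical(agg[pos3 == 1301L]$n_detected, 1L)
  # merge window unifies near-identical breakpoints
  agg2 <- aggregate_calls(calls, md, merge_window_bp = 2L)
  expect_identical(nrow(agg2), 1L)
  expect_identical(agg2$n_detected, 6L)
  expect_error(aggregate_calls(calls, md[1:2]), "absent from metadata")
})

test_that("recurrence filter boundary is >= min_recurrence", {
  md <- data.table::data.table(sample_id = paste0("S", 1:9),
                               sex = rep(c("F", "M"), c(5, 4)))
  calls <- data.table::rbindlist(c(
    lapply(paste0("S", 1:5), make_call),
    lapply(paste0("S", 1:4), make_call, pos3 = 1100L)))
  agg <- aggregate_calls(calls, md)
  r5 <- recurrence_filter(agg, 5L)
  expect_identical(r5$kept$pos3, 1300L)
  expect_match(r5$removed$reason, "4 < 5")
  r1 <- recurrence_filter(agg, 1L)
  expect_identical(nrow(r1$kept), 2L)
})

test_that("run_screen applies the stages in order with exact accounting", {
  fx <- screen_fixture()
  scr <- run_screen(fx$calls, fx$metadata, fx$annotation, fx$transcripts,
                    filter_config(min_recurrence = 2L))
  sc <- scr$stage_counts
  expect_identical(sc$stage,
                   c("score", "homology", "classify", "drop_mm", "aggregate",
                     "recurrence"))
  expect_identical(sc$kept_n, c(8L, 7L, 7L, 6L, 2L, 2L))
  expect_identical(sc$input_n[1], 10L)
  expect_identical(sc[stage == "aggregate"]$calls_in, 6L)
  # conservation at every stage and chaining within each unit
  expect_true(all(sc$input_n == sc$kept_n + sc$removed_n))
  calls_stages <- sc[unit == "calls"]
  expect_identical(calls_stages$input_n[-1],
                   calls_stages$kept_n[-nrow(calls_stages)])
  expect_identical(sc[stage == "recurrence"]$input_n,
                   sc[stage == "aggregate"]$kept_n)
  # every removed call is accounted for with a stage and reason
  expect_identical(nrow(scr$rejects), 4L)
  expect_setequal(scr$rejects$stage, c("score", "homology", "drop_mm"))
  # survivors
  expect_setequal(scr$aggregates$gene5, c("G1U", "G4U"))
  expect_identical(sort(scr$aggregates$n_detected), c(2L, 4L))
})

test_that("min_recurrence 5 removes every fixture chimera", {
  fx <- screen_fixture()
  scr <- run_screen(fx$calls, fx$metadata, fx$annotation, fx$transcripts,
                    filter_config(min_recurrence = 5L))
  expect_identical(nrow(scr$aggregates), 0L)
})

test_that("drop_MM = FALSE lets M/M calls reach aggregation", {
  fx <- screen_fixture()
  scr <- run_screen(fx$calls, fx$metadata, fx$annotation, fx$transcripts,
                    filter_config(min_recurrence = 1L, drop_MM = FALSE))
  expect_true("MM" %in% scr$aggregates$junction_class)
  expect_false("drop_mm" %in% scr$stage_counts$stage)
})

test_that("score and homology filters commute", {
  fx <- screen_fixture()
  a <- score_filter(fx$calls, 0.6)$kept
  a <- homology_filter(a, fx$transcripts, 0.9)$kept
  b <- homology_filter(fx$calls, fx$transcripts, 0.9)$kept
  b <- score_filter(b, 0.6)$kept
  data.table::setorder(a, sample_id, gene5)
  data.table::setorder(b, sample_id, gene5)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("filter_config validates its ranges", {
  expect_error(filter_config(min_score = 1.5))
  expect_error(filter_config(identity_threshold = 0))
  expect_error(filter_config(min_recurrence = 0))
})
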