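test_that("sex contingency tables are built from detection counts", {
  t1 <- sex_contingency(24, 0, 157, 268)
  expect_identical(t1, list(a = 24L, b = 133L, c = 0L, d = 268L))
  t2 <- sex_contingency(0, 0, 10, 20)
  expect_identical(t2, list(a = 0L, b = 10L, c = 0L, d = 20L))
  t3 <- sex_contingency(474, 173, 525, 727)
  expect_identical(t3, list(a = 474L, b = 51L, c = 173L, d = 554L))
  expect_error(sex_contingency(11, 0, 10, 20), "exceed")
})

test_that("Pearson chi-squared matches its derived values on printed tables", {
  r <- pearson_chi2(list(a = 24, b = 133, c = 0, d = 268))
  expect_equal(r$chi2, 43.42, tolerance = 1e-3)
  expect_equal(r$p, 4.4e-11, tolerance = 0.05)
  r2 <- pearson_chi2(list(a = 474, b = 51, c = 173, d = 554))
  expect_equal(r2$chi2, 539.7, tolerance = 1e-3)
  flat <- pearson_chi2(list(a = 10, b = 90, c = 10, d = 90))
  expect_identical(flat$chi2, 0)
  expect_identical(flat$p, 1)
  # zero column margin: untestable, not a number
  z <- pearson_chi2(list(a = 0, b = 100, c = 0, d = 200))
  expect_true(z$untestable)
  expect_true(is.na(z$chi2))
  expect_error(pearson_chi2(list(a = -1, b = 1, c = 1, d = 1)), "negative")
  expect_error(pearson_chi2(list(a = 0, b = 0, c = 1, d = 1)), "row margin")
})

test_that("closed form equals sum((O-E)^2/E) and chisq.test on random tables", {
  set.seed(17)
  for (i in 1:1000) {
    tab <- list(a = sample(0:50, 1), b = sample(1:200, 1),
                c = sample(0:50, 1), d = sample(1:200, 1))
    r <- pearson_chi2(tab)
    if (r$untestable) next
    o <- c(tab$a, tab$b, tab$c, tab$d)
    n <- sum(o)
    e <- c((tab$a + tab$b) * (tab$a + tab$c), (tab$a + tab$b) * (tab$b + tab$d),
           (tab$c + tab$d) * (tab$a + tab$c), (tab$c + tab$d) * (tab$b + tab$d)) / n
    expect_equal(r$chi2, sum((o - e)^2 / e), tolerance = 1e-9)
  }
  tab <- list(a = 24, b = 133, c = 7, d = 261)
  ct <- suppressWarnings(stats::chisq.test(matrix(unlist(tab), 2, byrow = TRUE),
                                           correct = FALSE))
  r <- pearson_chi2(tab)
  expect_equal(r$chi2, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
})

test_that("Fisher exact agrees with enumeration and stats::fisher.test", {
  expect_identical(fisher_exact(list(a = 1, b = 0, c = 0, d = 1)), 1)
  expect_equal(fisher_exact(list(a = 5, b = 0, c = 0, d = 5)), 2 / 252)
  expect_identical(fisher_exact(list(a = 3, b = 3, c = 3, d = 3)), 1)
  expect_error(fisher_exact(list(a = 0, b = 0, c = 0, d = 0)), "zero")

  # independent oracle: enumerate all tables with fixed margins, point
  # probabilities from explicit factorial products
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c; N <- m + n
    lp <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(N, k)
    xs <- max(0, k - n):min(k, m)
    probs <- exp(lp(xs))
    sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
  }
  set.seed(23)
  for (i in 1:200) {
    cells <- as.list(stats::setNames(sample(0:8, 4, TRUE), c("a", "b", "c", "d")))
    if (sum(unlist(cells)) == 0 || sum(unlist(cells)) > 30) next
    p <- fisher_exact(cells)
    expect_equal(p, enum_fisher(cells$a, cells$b, cells$c, cells$d),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(unlist(cells), 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
})

test_that("chi-squared and Fisher agree within 2x when expected cells >= 20", {
  set.seed(41)
  n_checked <- 0
  while (n_checked < 50) {
    a <- sample(30:120, 1); b <- sample(30:120, 1)
    c_ <- sample(30:120, 1); d <- sample(30:120, 1)
    tab <- list(a = a, b = b, c = c_, d = d)
    n <- a + b + c_ + d
    e <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
    if (min(e) < 20) next
    pc <- pearson_chi2(tab)$p
    pf <- fisher_exact(tab)
    if (pc < 1e-12) next  # ratios meaningless at underflow
    expect_lt(abs(log(pc / pf)), log(2))
    n_checked <- n_checked + 1
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_identical(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("sex association flags chimeras at the -log10(alpha) cutoff", {
  agg <- data.table::data.table(
    gene5 = c("GA", "GB", "GC"), gene3 = c("GX", "GY", "GZ"),
    chrom5 = "chr1", pos5 = c(100L, 200L, 300L), chrom3 = "chr1",
    pos3 = c(150L, 250L, 350L),
    n_detected = c(24L, 20L, 0L),
    n_female_detected = c(24L, 8L, 0L),
    n_male_detected = c(0L, 12L, 0L))
  res <- sex_association(agg, n_female = 157, n_male = 268)
  expect_identical(res$significant, c(TRUE, FALSE, FALSE))
  expect_true(res$untestable[3])
  expect_equal(res$pct_female[1], 100)
  expect_equal(res$total_detected[1:2], c(24L, 20L))
  expect_true(all(res$neg_log10_p[1] > res$neg_log10_p[2]))
  # pct_female depends only on detected counts, not cohort sizes
  res2 <- sex_association(agg, n_female = 500, n_male = 600)
  expect_equal(res2$pct_female, res$pct_female)
  # BH-adjusted p reported but not used for the flag
  expect_true(all(res$p_adjusted[1:2] >= res$p[1:2]))
})

test_that("bubble table ranks by 5' genomic position with the 1.3 cutoff", {
  agg <- data.table::data.table(
    gene5 = c("GB", "GA"), gene3 = c("GY", "GX"),
    chrom5 = "chr1", pos5 = c(5000L, 100L), chrom3 = "chr1",
    pos3 = c(5100L, 300L),
    n_detected = c(24L, 10L), n_female_detected = c(24L, 5L),
    n_male_detected = c(0L, 5L))
  res <- sex_association(agg, 157, 268)
  bub <- bubble_table(res)
  expect_equal(bub$cutoff_line, -log10(0.05))
  expect_identical(round(bub$cutoff_line, 1), 1.3)
  expect_identical(bub$rows$label, c("GA-GX", "GB-GY"))  # genomic order
  expect_identical(bub$rows$x, 1:2)
  gtex_like <- bub$rows[label == "GB-GY"]
  expect_identical(gtex_like$size, 24L)
  expect_equal(gtex_like$color, 100)
  # p = 1 maps to y = 0
  flat <- sex_association(data.table::data.table(
    gene5 = "G", gene3 = "H", chrom5 = "c", pos5 = 1L, chrom3 = "c",
    pos3 = 2L, n_detected = 20L, n_female_detected = 10L,
    n_male_detected = 10L), 100, 100)
  expect_equal(bubble_table(flat)$rows$y, 0)
  # untestable chimeras excluded with a logged count
  both <- rbind(res, sex_association(data.table::data.table(
    gene5 = "GZ", gene3 = "GW", chrom5 = "chr1", pos5 = 9000L,
    chrom3 = "chr1", pos3 = 9100L, n_detected = 0L,
    n_female_detected = 0L, n_male_detected = 0L), 157, 268))
  expect_message(b2 <- bubble_table(both), "1 untestable")
  expect_identical(nrow(b2$rows), 2L)
  expect_identical(b2$n_untestable, 1L)
})
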