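#' Build the per-chimera sex 2x2 contingency table
#'
#' Rows are sex, columns detection status: `a` = females with the chimera
#' detected, `b` = females without, `c` = males with, `d` = males without.
#'
#' @param n_female_detected,n_male_detected Individuals of each sex in
#'   which the chimera was detected.
#' @param n_female,n_male Cohort totals by sex.
#' @return List with integer cells `a`, `b`, `c`, `d`.
#' @export
sex_contingency <- function(n_female_detected, n_male_detected,
                            n_female, n_male) {
  a <- as.integer(n_female_detected); c_ <- as.integer(n_male_detected)
  if (a > n_female) stop("detected females (", a, ") exceed cohort females (",
                         n_female, ")")
  if (c_ > n_male) stop("detected males (", c_, ") exceed cohort males (",
                        n_male, ")")
  if (min(a, c_) < 0L) stop("negative detection count")
  list(a = a, b = as.integer(n_female) - a,
       c = c_, d = as.integer(n_male) - c_)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one degree
#' of freedom and no continuity correction. A table with a zero column
#' margin (detected by nobody, or by everybody) has no association to test
#' and is returned flagged `untestable` rather than as a number.
#'
#' @param table A list/vector with cells `a`, `b`, `c`, `d`
#'   (see [sex_contingency()]).
#' @return List with `chi2`, `p` (upper tail of the chi-squared
#'   distribution) and `untestable`.
#' @export
pearson_chi2 <- function(table) {
  a <- as.double(table$a); b <- as.double(table$b)
  c_ <- as.double(table$c); d <- as.double(table$d)
  if (min(a, b, c_, d) < 0) stop("negative cell in contingency table")
  if (a + b == 0 || c_ + d == 0) stop("zero row margin (empty sex stratum)")
  if (a + c_ == 0 || b + d == 0)
    return(list(chi2 = NA_real_, p = NA_real_, untestable = TRUE))
  n <- a + b + c_ + d
  chi2 <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       untestable = FALSE)
}

#' Fisher exact test on a 2x2 table (two-sided)
#'
#' Sums hypergeometric point probabilities not exceeding that of the
#' observed table, with all margins fixed. Companion to [pearson_chi2()]
#' for small or zero-cell tables.
#'
#' @inheritParams pearson_chi2
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (min(a, b, c_, d) < 0) stop("negative cell in contingency table")
  if (a + b + c_ + d == 0) stop("all cells zero")
  m <- a + b; n <- c_ + d; k <- a + c_
  x <- max(0L, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (monotone, capped at 1).
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Sex-association testing of surviving chimeras
#'
#' Builds the 2x2 detection-by-sex table for every chimera aggregate and
#' applies [pearson_chi2()] (headline statistic) and [fisher_exact()]
#' (exact companion). Significance is called on the raw Pearson p at
#' `-log10(p) >= -log10(alpha)` — the bubble-plot cutoff — with BH-adjusted
#' values reported alongside, not used for the flag.
#'
#' @param aggregates Output of [aggregate_calls()]/[run_screen()].
#' @param n_female,n_male Cohort totals by sex.
#' @param alpha Significance level for the cutoff line (default 0.05).
#' @return The aggregate table with `chi2`, `p`, `neg_log10_p`,
#'   `fisher_p`, `p_adjusted`, `pct_female`, `total_detected`,
#'   `significant` and `untestable` columns appended.
#' @export
sex_association <- function(aggregates, n_female, n_male, alpha = 0.05) {
  agg <- as.data.table(aggregates)
  cutoff <- -log10(alpha)
  res <- lapply(seq_len(nrow(agg)), function(i) {
    tab <- sex_contingency(agg$n_female_detected[i], agg$n_male_detected[i],
                           n_female, n_male)
    chi <- pearson_chi2(tab)
    data.table(
      chi2 = chi$chi2, p = chi$p,
      neg_log10_p = if (chi$untestable) NA_real_ else -log10(chi$p),
      fisher_p = if (chi$untestable) NA_real_ else fisher_exact(tab),
      pct_female = 100 * tab$a / (tab$a + tab$c),
      total_detected = tab$a + tab$c,
      untestable = chi$untestable)
  })
  out <- cbind(agg, rbindlist(res))
  out[, p_adjusted := NA_real_]
  out[untestable == FALSE, p_adjusted := bh_adjust(p)]
  out[, significant := !untestable & neg_log10_p >= cutoff]
  out[]
}

#' Bubble-plot table
#'
#' One row per tested chimera: x = genomic rank of the 5' breakpoint,
#' y = -log10(p) of the sex-association test, bubble size = number of
#' individuals with the chimera, colour = percentage of those that are
#' female. The cutoff line is -log10(alpha), i.e. 1.3 at alpha = 0.05.
#' Untestable chimeras are excluded and counted.
#'
#' @param results Output of [sex_association()].
#' @param alpha Significance level defining the cutoff line.
#' @return List with `rows` (`data.table`: `x`, `y`, `size`, `color`,
#'   `label`), `cutoff_line` and `n_untestable`.
#' @export
bubble_table <- function(results, alpha = 0.05) {
  res <- as.data.table(results)
  n_untestable <- sum(res$untestable)
  res <- res[untestable == FALSE]
  setorder(res, chrom5, pos5, gene5, gene3, pos3)
  rows <- res[, .(x = seq_len(.N), y = neg_log10_p, size = total_detected,
                  color = pct_female, label = paste0(gene5, "-", gene3))]
  if (n_untestable)
    message(n_untestable, " untestable chimera(s) excluded from bubble table")
  list(rows = rows, cutoff_line = -log10(alpha), n_untestable = n_untestable)
}

#' Render the bubble plot
#'
#' @param bubble Output of [bubble_table()].
#' @param path Optional output file (PNG/SVG/PDF by extension).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_bubble <- function(bubble, path = NULL) {
  rows <- as.data.frame(bubble$rows)
  gp <- ggplot2::ggplot(rows, ggplot2::aes(x = x, y = y,
                                           size = size, color = color)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = bubble$cutoff_line, linetype = "dashed") +
    ggplot2::scale_color_gradient(low = "#2166ac", high = "#b2182b",
                                  name = "% female") +
    ggplot2::scale_size_area(name = "individuals") +
    ggplot2::labs(x = "chimeric RNAs (genomic order of 5' breakpoint)",
                  y = expression(-log[10] * italic(P))) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gp, width = 7, height = 4, dpi = 150)
    return(invisible(gp))
  }
  gp
}

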