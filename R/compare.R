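#' Per-interval chi-square scan between two populations
#'
#' For every SNP interval, tests whether the proportion of crossover mass per
#' meiosis differs between two populations with a Pearson chi-square on the
#' 2x2 table `[mass, meioses - mass]` by population (1 df). Crossover masses
#' are fractional (even assignment across informative gaps) and are used as
#' table entries without rounding, so the statistic is asymptotic and
#' approximate when masses are small. No continuity correction is applied.
#' Significance is flagged at the Bonferroni level `alpha / n_testable`.
#'
#' @param det_a,det_b lists with `records` and `masses` for each population
#'   (QC-passed meioses, already restricted to one sex).
#' @param snps the shared SNP table.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.table with one row per interval: name, chrom, bp, interval,
#'   mass_a, mass_b, n_a, n_b, stat, p, sig, testable. Intervals with zero
#'   total mass (or degenerate tables) are recorded untestable with `NA`
#'   statistic.
#' @export
interval_chisq_scan <- function(det_a, det_b, snps, alpha = 0.05) {
  snps <- as.data.table(snps)
  n_a <- nrow(det_a$records)
  n_b <- nrow(det_b$records)
  stopifnot(n_a > 0, n_b > 0)
  iv <- which(!chrom_first(snps))
  x_a <- numeric(nrow(snps)); x_b <- numeric(nrow(snps))
  agg_a <- as.data.table(det_a$masses)[, .(mass = sum(mass)), by = interval]
  agg_b <- as.data.table(det_b$masses)[, .(mass = sum(mass)), by = interval]
  x_a[agg_a$interval] <- agg_a$mass
  x_b[agg_b$interval] <- agg_b$mass
  x_a <- x_a[iv]; x_b <- x_b[iv]
  testable <- (x_a + x_b) > 0 & x_a < n_a & x_b < n_b
  stat <- rep(NA_real_, length(iv))
  N <- n_a + n_b
  num <- (x_a * (n_b - x_b) - (n_a - x_a) * x_b)^2
  den <- as.numeric(n_a) * n_b * (x_a + x_b) * (N - x_a - x_b)
  stat[testable] <- N * num[testable] / den[testable]
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  n_test <- sum(testable)
  thr <- alpha / n_test
  out <- data.table(
    name = snps$name[iv], chrom = snps$chrom[iv], bp = snps$bp[iv],
    interval = iv, mass_a = x_a, mass_b = x_b, n_a = n_a, n_b = n_b,
    stat = stat, p = p, sig = !is.na(p) & p < thr, testable = testable
  )
  setattr(out, "alpha", alpha)
  setattr(out, "bonferroni", thr)
  out
}
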