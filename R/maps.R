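#' Build a recombination map from detected meioses
#'
#' The rate of interval `i` is the mean crossover mass per meiosis landing in
#' it, so the genome-wide rate sum equals the mean genome-wide crossover count
#' of the contributing meioses. Callers are expected to pass meioses already
#' restricted to the intended breed/sex/density subset, or use the `breed` and
#' `sex` filters.
#'
#' @param records,masses tables from [detect_crossovers()] (after
#'   [qc_filter_meioses()]).
#' @param snps the ordered SNP table the interval indices refer to.
#' @param breed,sex optional filters; also stored as map labels.
#' @return object of class `rec_map`: list(breed, sex, n_meioses, snps, rate)
#'   with `rate` a numeric vector over SNP rows (0 on chromosome-first rows).
#' @export
build_recmap <- function(records, masses, snps, breed = NULL, sex = NULL) {
  records <- as.data.table(records)
  masses <- as.data.table(masses)
  if (!is.null(breed)) {
    keep <- records$breed == breed
    records <- records[keep]
  }
  if (!is.null(sex)) {
    keep <- records$sex == sex
    records <- records[keep]
  }
  n <- nrow(records)
  if (n == 0L) stop("build_recmap: no meioses after filtering")
  mm <- masses[meiosis %in% records$meiosis]
  rate <- numeric(nrow(snps))
  if (nrow(mm)) {
    agg <- mm[, .(mass = sum(mass)), by = interval]
    rate[agg$interval] <- agg$mass / n
  }
  structure(list(breed = breed %||% records$breed[1L],
                 sex = sex %||% records$sex[1L],
                 n_meioses = n, snps = as.data.table(snps), rate = rate),
            class = "rec_map")
}

#' @export
print.rec_map <- function(x, ...) {
  cat("rec_map:", x$breed, x$sex, "-", x$n_meioses, "meioses,",
      sum(!chrom_first(x$snps)), "intervals, genome length",
      round(map_length(x), 3), "crossovers/meiosis\n")
  invisible(x)
}

#' Genome-wide map length (expected crossovers per meiosis)
#'
#' @param map a [build_recmap()] object.
#' @return sum of interval rates.
#' @export
map_length <- function(map) {
  stopifnot(inherits(map, "rec_map"))
  sum(map$rate)
}

#' Genome-wide recombination rate from accounting totals
#'
#' The map-level identity `rate = total crossovers / meioses` applied to
#' plain counts, as used in per-breed accounting tables.
#'
#' @param crossovers total crossover count.
#' @param meioses number of meioses.
#' @return crossovers per meiosis.
#' @export
genomewide_recombination_rate <- function(crossovers, meioses) {
  stopifnot(meioses > 0, crossovers >= 0)
  crossovers / meioses
}

#' Pearson correlation between two recombination maps
#'
#' Computed over interval rows only (chromosome-first rows carry no interval).
#' A zero-variance map has no defined correlation and yields `NA` with a
#' warning.
#'
#' @param a,b [build_recmap()] objects on the same SNP set.
#' @return correlation coefficient, or `NA_real_` if undefined.
#' @export
map_correlation <- function(a, b) {
  stopifnot(inherits(a, "rec_map"), inherits(b, "rec_map"))
  if (!same_snps(a$snps, b$snps)) stop("maps are on different SNP sets")
  iv <- !chrom_first(a$snps)
  x <- a$rate[iv]; y <- b$rate[iv]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("map_correlation undefined: zero-variance map")
    return(NA_real_)
  }
  cor(x, y)
}

#' Equal-sample-size map correlations by resampling
#'
#' Unequal numbers of meioses inflate apparent map differences; this draws the
#' same number of meioses from every population, rebuilds the maps, correlates
#' all pairs, and averages over replicates.
#'
#' @param dets named list, one entry per population, each a list with
#'   `records` and `masses` (QC-passed meioses).
#' @param snps the shared SNP table.
#' @param k meioses drawn per population and replicate (without replacement).
#' @param reps number of replicates.
#' @return list with `mean_cor` (matrix of element-wise mean correlations,
#'   diagonal 1) and `reps`, `k`.
#' @export
equal_sample_correlation <- function(dets, snps, k, reps = 1000L) {
  stopifnot(length(dets) >= 2, !is.null(names(dets)))
  sizes <- vapply(dets, function(d) nrow(d$records), 0L)
  if (any(k > sizes))
    stop("k = ", k, " exceeds the smallest population (", min(sizes),
         " meioses)")
  nb <- length(dets)
  acc <- matrix(0, nb, nb, dimnames = list(names(dets), names(dets)))
  for (r in seq_len(reps)) {
    maps <- lapply(dets, function(d) {
      ids <- d$records$meiosis[sample.int(nrow(d$records), k)]
      build_recmap(d$records[meiosis %in% ids],
                   d$masses[meiosis %in% ids], snps)
    })
    for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
      cc <- map_correlation(maps[[i]], maps[[j]])
      acc[i, j] <- acc[i, j] + cc
    }
  }
  m <- acc / reps
  m <- m + t(m)
  diag(m) <- 1
  list(mean_cor = m, reps = reps, k = k)
}

#' Smoothed recombination profile over relative chromosome position
#'
#' Every interval contributes a point at its midpoint position standardized by
#' chromosome length (0 = chromosome start, 1 = end) with its rate normalized
#' per Mb (interval widths vary); one cubic smoothing spline is fitted across
#' all chromosomes pooled.
#'
#' @param map a [build_recmap()] object.
#' @param spar smoothing parameter in (0, 1] passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by generalized
#'   cross-validation.
#' @param n_points number of evaluation points on `[0, 1]`.
#' @return list with `profile` (data.table: position, rate — smoothed rate per
#'   Mb per meiosis) and `points` (the raw per-interval points).
#' @export
position_profile <- function(map, spar = NULL, n_points = 200L) {
  stopifnot(inherits(map, "rec_map"))
  if (!is.null(spar) && (spar <= 0 || spar > 1))
    stop("spar must be in (0, 1]")
  snps <- map$snps
  first <- chrom_first(snps)
  w <- interval_width(snps)
  iv <- which(!first)
  chrom_len <- tapply(snps$bp, snps$chrom, max)
  mid <- (snps$bp[iv] + snps$bp[iv - 1L]) / 2
  pts <- data.table(
    position = mid / as.numeric(chrom_len[as.character(snps$chrom[iv])]),
    rate_mb = map$rate[iv] / w[iv] * 1e6
  )
  fit <- if (is.null(spar)) smooth.spline(pts$position, pts$rate_mb)
  else smooth.spline(pts$position, pts$rate_mb, spar = spar)
  grid <- seq(0, 1, length.out = n_points)
  prof <- data.table(position = grid,
                     rate = predict(fit, grid)$y)
  list(profile = prof, points = pts)
}
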