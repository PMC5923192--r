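#' Hotspot-calling criteria
#'
#' @param multiplier number of standard deviations above the mean interval
#'   rate a hotspot region must exceed (default 2.5).
#' @return object of class `hotspot_criteria`.
#' @export
hotspot_criteria <- function(multiplier = 2.5) {
  stopifnot(multiplier > 0)
  structure(list(multiplier = multiplier), class = "hotspot_criteria")
}

#' Call hotspot regions in a recombination map
#'
#' A hotspot region is a SNP interval whose rate strictly exceeds
#' `mean + multiplier * sd` of all interval rates (population standard
#' deviation over every autosomal interval, zeros included). At typical SNP
#' panel spacing these regions are tens of kb wide — much coarser than
#' kb-scale hotspots mapped in humans or mice.
#'
#' @param map a [build_recmap()] object.
#' @param criteria a [hotspot_criteria()].
#' @return object of class `hotspot_set`: list(breed, sex, intervals =
#'   integer SNP-row indices of flagged intervals, threshold, n_intervals,
#'   snps).
#' @export
call_hotspots <- function(map, criteria = hotspot_criteria()) {
  stopifnot(inherits(map, "rec_map"), inherits(criteria, "hotspot_criteria"))
  iv <- which(!chrom_first(map$snps))
  if (length(iv) < 2L)
    stop("call_hotspots: fewer than two intervals, sd undefined")
  r <- map$rate[iv]
  thr <- mean(r) + criteria$multiplier * pop_sd(r)
  structure(list(breed = map$breed, sex = map$sex,
                 intervals = iv[r > thr], threshold = thr,
                 n_intervals = length(iv), snps = map$snps),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("hotspot_set:", x$breed, x$sex, "-", length(x$intervals), "of",
      x$n_intervals, "intervals above", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Sharing structure of several hotspot sets
#'
#' Partitions the union of the sets by exact membership pattern (Venn-style
#' exclusive counts), and additionally reports the counts usually quoted:
#' regions shared by all sets, regions unique to each set, and pairwise
#' shared counts excluding the all-shared core.
#'
#' @param sets named list of two or more [call_hotspots()] results over the
#'   same interval universe.
#' @return list with `partition` (data.table: membership pattern, count),
#'   `all_shared`, `unique` (named vector), `pairwise` (data.table: set_a,
#'   set_b, shared_excl_core) and `union_size`.
#' @export
hotspot_sharing <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  for (s in sets) stopifnot(inherits(s, "hotspot_set"))
  n_univ <- unique(vapply(sets, function(s) s$n_intervals, 0L))
  if (length(n_univ) != 1L)
    stop("hotspot sets are on different interval universes")
  univ <- sort(unique(unlist(lapply(sets, function(s) s$intervals))))
  memb <- vapply(sets, function(s) univ %in% s$intervals,
                 logical(length(univ)))
  memb <- matrix(memb, nrow = length(univ),
                 dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(z) paste(names(sets)[z], collapse = "+"))
  partition <- data.table(pattern = pattern)[, .N, by = pattern]
  setnames(partition, "N", "count")
  all_shared <- sum(rowSums(memb) == ncol(memb))
  uniq <- colSums(memb & rowSums(memb) == 1L)
  pairs <- utils::combn(names(sets), 2L)
  pairwise <- data.table(
    set_a = pairs[1L, ], set_b = pairs[2L, ],
    shared_excl_core = apply(pairs, 2L, function(pp) {
      sum(memb[, pp[1L]] & memb[, pp[2L]]) - all_shared
    })
  )
  list(partition = partition, all_shared = all_shared, unique = uniq,
       pairwise = pairwise, union_size = length(univ))
}
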