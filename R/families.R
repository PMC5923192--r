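#' Extract analyzable three-generation families
#'
#' A family is one (offspring, donor parent) pair in which the offspring, the
#' donor and at least one of the donor's parents are genotyped; crossovers are
#' then detectable in the donor's meiosis that produced the offspring. An
#' offspring contributes up to two families, one per genotyped parent side.
#' Each family is classified by SNP panel density: the minimum typed-marker
#' count of the offspring-donor pair against `density_threshold` (detection
#' resolution is limited by the least-dense member).
#'
#' @param cohort a [new_cohort()] object with an acyclic pedigree.
#' @param density_threshold typed-marker count at or above which a family is
#'   classed high-density (the "at least 50K chip" restriction; default
#'   50000).
#' @return list with `families` (data.table: offspring, donor, donor_sex,
#'   breed, gp_sire, gp_dam, density_min, density_class with levels
#'   `"lt"`/`"ge"`) and `summary` (see [summarize_family_counts()]).
#' @export
extract_families <- function(cohort, density_threshold = 50000) {
  stopifnot(inherits(cohort, "cohort"))
  ped <- cohort$ped
  .check_acyclic(ped)
  typed <- cohort$panel
  genotyped <- names(typed)[typed > 0L]
  parent_of <- ped[, .(id, sire, dam)]
  setkey(parent_of, id)
  out <- list()
  for (role in c("sire", "dam")) {
    pairs <- ped[id %in% genotyped & !is.na(get(role)) &
                   get(role) %in% genotyped,
                 .(offspring = id, donor = get(role), breed)]
    if (!nrow(pairs)) next
    gp <- parent_of[J(pairs$donor)]
    keep <- (!is.na(gp$sire) & gp$sire %in% genotyped) |
      (!is.na(gp$dam) & gp$dam %in% genotyped)
    pairs <- pairs[keep]
    gp <- gp[keep]
    if (!nrow(pairs)) next
    pairs[, `:=`(
      donor_sex = if (role == "sire") "male" else "female",
      gp_sire = fifelse(!is.na(gp$sire) & gp$sire %in% genotyped,
                        gp$sire, NA_character_),
      gp_dam = fifelse(!is.na(gp$dam) & gp$dam %in% genotyped,
                       gp$dam, NA_character_),
      density_min = pmin(typed[offspring], typed[donor])
    )]
    out[[role]] <- pairs
  }
  fams <- rbindlist(out, use.names = TRUE)
  if (nrow(fams)) {
    fams[, density_class := fifelse(density_min >= density_threshold,
                                    "ge", "lt")]
    setcolorder(fams, c("offspring", "donor", "donor_sex", "breed",
                        "gp_sire", "gp_dam", "density_min", "density_class"))
    setorder(fams, breed, donor_sex, offspring)
  } else {
    fams <- data.table(offspring = character(), donor = character(),
                       donor_sex = character(), breed = character(),
                       gp_sire = character(), gp_dam = character(),
                       density_min = integer(), density_class = character())
  }
  list(families = fams, summary = family_summary(fams))
}

#' Tabulate families by breed, donor sex and density class
#'
#' @param families the `families` table from [extract_families()].
#' @return the [summarize_family_counts()] table.
#' @export
family_summary <- function(families) {
  cells <- dcast(
    as.data.table(families)[, .N, by = .(breed, donor_sex, density_class)],
    breed ~ donor_sex + density_class, value.var = "N", fill = 0L
  )
  for (cn in c("male_lt", "male_ge", "female_lt", "female_ge"))
    if (!cn %in% names(cells)) cells[, (cn) := 0L]
  summarize_family_counts(
    cells[, .(breed, male_lt, male_ge, female_lt, female_ge)])
}

#' Totals and shares for a breed x sex x density count table
#'
#' Takes the four sex-by-density cell counts per breed (low/high density for
#' male and female meioses), appends each breed's total and its percentage of
#' the grand total, and a grand-total row. Printed cohort-accounting tables of
#' this shape can be fed in directly.
#'
#' @param cells data.frame/data.table with columns `breed`, `male_lt`,
#'   `male_ge`, `female_lt`, `female_ge`.
#' @return data.table with added `total` and `pct` columns and a final `Total`
#'   row; `pct` is the share of the grand total in percent (1 decimal).
#' @export
summarize_family_counts <- function(cells) {
  cells <- as.data.table(cells)
  need <- c("breed", "male_lt", "male_ge", "female_lt", "female_ge")
  stopifnot(all(need %in% names(cells)))
  out <- cells[, ..need]
  out[, total := male_lt + male_ge + female_lt + female_ge]
  grand <- sum(out$total)
  out[, pct := round(100 * total / grand, 1)]
  tot <- data.table(breed = "Total",
                    male_lt = sum(out$male_lt), male_ge = sum(out$male_ge),
                    female_lt = sum(out$female_lt),
                    female_ge = sum(out$female_ge),
                    total = grand, pct = 100)
  rbind(out, tot)
}

# reject pedigrees with ancestry cycles; name the cycle members
.check_acyclic <- function(ped) {
  ids <- ped$id
  idx <- setNames(seq_along(ids), ids)
  parents <- lapply(seq_len(nrow(ped)), function(i) {
    p <- c(ped$sire[i], ped$dam[i])
    unname(idx[p[!is.na(p) & p %in% ids]])
  })
  indeg <- lengths(parents)
  children <- vector("list", length(ids))
  for (i in seq_along(parents))
    for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids))
    stop("pedigree contains a cycle involving: ",
         paste(ids[indeg > 0L], collapse = ", "))
  invisible(TRUE)
}
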