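#' Quality-control configuration for crossover detection
#'
#' @param max_crossovers meioses with strictly more genome-wide crossovers
#'   than this are removed (default 45, the tail cut used for pedigree SNP
#'   data; the comparison is strict, so 45 is retained).
#' @param min_support minimum number of consecutive informative sites that
#'   must agree before a template switch is accepted; shorter runs are treated
#'   as genotyping error and masked (default 2).
#' @param max_mendel_rate families whose donor shows Mendelian-error sites in
#'   excess of this fraction of its typed markers are dropped (default 0.02).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(max_crossovers = 45L, min_support = 2L,
                      max_mendel_rate = 0.02) {
  stopifnot(max_crossovers >= 1, min_support >= 1,
            max_mendel_rate >= 0, max_mendel_rate <= 1)
  structure(list(max_crossovers = as.integer(max_crossovers),
                 min_support = as.integer(min_support),
                 max_mendel_rate = max_mendel_rate),
            class = "qc_config")
}

#' Trace template switches along the transmitted haplotype
#'
#' At every informative site the transmitted allele matches exactly one donor
#' haplotype. Within each chromosome the matched template is followed along
#' the informative sites; a crossover is emitted between consecutive sites
#' whose template differs. Runs of fewer than `min_support` agreeing sites are
#' masked as likely genotyping error and tracing is repeated until stable, so
#' an isolated discordant site never produces a double crossover. Sites where
#' the transmitted allele is unknown are skipped. Switches need evidence on
#' both sides, so crossovers beyond the terminal informative sites of a
#' chromosome are undetectable and not imputed.
#'
#' @param transmitted integer allele vector (0/1/NA) the offspring inherited
#'   from the donor, over all SNPs.
#' @param donor the donor's [phase_trio()] result.
#' @param inf_sites site indices from [informative_sites()].
#' @param chrom per-SNP chromosome vector.
#' @param min_support see [qc_config()].
#' @return list with `switches` (data.table: chrom, `a`, `b` = SNP indices of
#'   the informative sites flanking each crossover), `n_used` informative
#'   sites with known transmitted allele, `n_masked` sites removed by the
#'   run filter, and `sites` (the surviving informative sites the template
#'   path is defined on).
#' @export
trace_crossovers <- function(transmitted, donor, inf_sites, chrom,
                             min_support = 2L) {
  keep <- inf_sites[!is.na(transmitted[inf_sites])]
  n_used <- length(keep)
  n_masked <- 0L
  sw <- list()
  surv <- list()
  for (cc in unique(chrom[keep])) {
    sites <- keep[chrom[keep] == cc]
    tmpl <- 1L + (transmitted[sites] != donor$h1[sites])   # 1 = h1, 2 = h2
    repeat {
      if (!length(sites)) break
      r <- rle(tmpl)
      short <- r$lengths < min_support
      if (!any(short)) break
      drop <- rep.int(short, r$lengths)
      n_masked <- n_masked + sum(drop)
      sites <- sites[!drop]
      tmpl <- tmpl[!drop]
    }
    surv[[as.character(cc)]] <- sites
    if (length(sites) < 2L) next
    r <- rle(tmpl)
    if (length(r$lengths) > 1L) {
      ends <- cumsum(r$lengths)
      a <- sites[ends[-length(ends)]]
      b <- sites[ends[-length(ends)] + 1L]
      sw[[as.character(cc)]] <- data.table(chrom = cc, a = a, b = b)
    }
  }
  switches <- if (length(sw)) rbindlist(sw)
  else data.table(chrom = integer(), a = integer(), b = integer())
  list(switches = switches, n_used = n_used, n_masked = n_masked,
       sites = unlist(surv, use.names = FALSE) %||% integer(0))
}

#' Distribute one crossover evenly over the SNP intervals it may occupy
#'
#' A switch observed between informative sites `a` and `b` localizes the
#' crossover only to the `b - a` underlying adjacent-SNP intervals; each
#' receives mass `1/(b - a)` so total mass 1 is conserved.
#'
#' @param a,b SNP row indices of the flanking informative sites, `a < b` on
#'   one chromosome.
#' @return data.table with `interval` (right-SNP row index) and `mass`.
#' @export
assign_crossover_mass <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L, b > a)
  k <- b - a
  data.table(interval = (a + 1L):b, mass = 1 / k)
}

#' Detect crossovers in all families of a cohort
#'
#' For each family the donor is phased against the grandparents, the offspring
#' against its parents, and the donor-transmitted offspring haplotype is
#' traced with [trace_crossovers()]. Each switch's mass is spread evenly over
#' the SNP intervals between its flanking informative sites. Families whose
#' donor exceeds the Mendelian-error threshold are dropped and logged.
#'
#' @param cohort a [new_cohort()] object.
#' @param families the `families` table from [extract_families()].
#' @param qc a [qc_config()].
#' @return object of class `xo_detection`: list with `records` (one row per
#'   meiosis: meiosis, offspring, donor, sex, breed, n_xo, n_inf_donor,
#'   n_inf_off, density, n_masked), `masses` (sparse: meiosis, interval,
#'   mass), `snps`, and `dropped` (families removed for Mendelian errors).
#' @export
detect_crossovers <- function(cohort, families, qc = qc_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(qc, "qc_config"))
  families <- as.data.table(families)
  snps <- cohort$snps
  geno <- cohort$geno
  chrom <- snps$chrom
  nfam <- nrow(families)
  ped <- cohort$ped
  sire_of <- setNames(ped$sire, ped$id)
  dam_of <- setNames(ped$dam, ped$id)
  g_row <- function(id) {
    if (!is.na(id) && id %in% rownames(geno)) geno[id, ] else NULL
  }
  r_mei <- character(nfam); r_nxo <- numeric(nfam)
  r_infd <- integer(nfam); r_info <- integer(nfam)
  r_masked <- integer(nfam)
  mass_mei <- vector("list", nfam)
  mass_int <- vector("list", nfam)
  mass_val <- vector("list", nfam)
  dropped <- logical(nfam)
  drop_reason <- character(nfam)
  for (i in seq_len(nfam)) {
    off <- families$offspring[i]
    don <- families$donor[i]
    donor_pp <- phase_trio(geno[don, ], g_row(sire_of[don]),
                           g_row(dam_of[don]))
    n_typed <- sum(geno[don, ] >= 0L)
    if (n_typed > 0L &&
        length(donor_pp$mendel) / n_typed > qc$max_mendel_rate) {
      dropped[i] <- TRUE
      drop_reason[i] <- sprintf("donor %s: %d Mendelian-error sites / %d typed",
                                don, length(donor_pp$mendel), n_typed)
      next
    }
    off_pp <- phase_trio(geno[off, ], g_row(sire_of[off]), g_row(dam_of[off]))
    transmitted <- if (families$donor_sex[i] == "male") off_pp$h1 else off_pp$h2
    inf <- informative_sites(donor_pp)
    tr <- trace_crossovers(transmitted, donor_pp, inf, chrom,
                           min_support = qc$min_support)
    mei_id <- paste0(don, ">", off)
    nsw <- nrow(tr$switches)
    if (nsw) {
      spans <- tr$switches$b - tr$switches$a
      mass_mei[[i]] <- rep.int(mei_id, sum(spans))
      mass_int[[i]] <- sequence(spans, from = tr$switches$a + 1L)
      mass_val[[i]] <- rep.int(1 / spans, spans)
    }
    r_mei[i] <- mei_id
    r_nxo[i] <- nsw
    r_infd[i] <- length(inf)
    r_info[i] <- tr$n_used
    r_masked[i] <- tr$n_masked
  }
  keep <- !dropped
  records <- data.table(
    meiosis = r_mei[keep], offspring = families$offspring[keep],
    donor = families$donor[keep], sex = families$donor_sex[keep],
    breed = families$breed[keep], n_xo = r_nxo[keep],
    n_inf_donor = r_infd[keep], n_inf_off = r_info[keep],
    density = as.integer(families$density_min[keep]),
    n_masked = r_masked[keep]
  )
  masses <- data.table(
    meiosis = as.character(unlist(mass_mei)),
    interval = as.integer(unlist(mass_int)),
    mass = as.numeric(unlist(mass_val)))
  structure(list(records = records, masses = masses, snps = snps,
                 dropped = families[dropped][, drop_reason := drop_reason[dropped]]),
            class = "xo_detection")
}

#' Remove meioses failing genome-wide crossover QC
#'
#' @param det an [detect_crossovers()] result (or a list with `records` and
#'   `masses`).
#' @param qc a [qc_config()]; meioses with `n_xo` strictly greater than
#'   `qc$max_crossovers` are removed.
#' @return list with filtered `records` and `masses` plus `excluded` (the
#'   removed records with their counts).
#' @export
qc_filter_meioses <- function(det, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  records <- as.data.table(det$records)
  bad <- records$n_xo > qc$max_crossovers
  out <- det
  out$records <- records[!bad]
  out$excluded <- records[bad]
  out$masses <- as.data.table(det$masses)[meiosis %in% out$records$meiosis]
  out
}
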