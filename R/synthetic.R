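#' Simulation configuration for synthetic genotyped cohorts
#'
#' Bundles and validates all parameters of the cohort simulator. The defaults
#' describe the study conditions the package targets: cattle-like autosomes,
#' a male genetic map of 24.8 and a female map of 22.5 expected crossovers per
#' meiosis (genome-wide totals observed in dairy cattle pedigrees), a small
#' fraction of hotspot intervals carrying strongly elevated intensity, and
#' clean (error-free, complete) genotypes unless degradation is requested.
#'
#' @param n_chromosomes number of autosomes to simulate.
#' @param snps_per_chromosome SNPs per autosome (all chromosomes equal).
#' @param chrom_length_bp physical chromosome length in bp; SNP positions are
#'   drawn uniformly without replacement in `[1, chrom_length_bp]`.
#' @param n_families three-generation families per breed. Each family
#'   contributes exactly one analyzable donor meiosis (offspring + genotyped
#'   donor parent + genotyped grandparents).
#' @param breeds character vector of breed labels.
#' @param map_length named numeric, expected genome-wide crossovers per
#'   meiosis for `male` and `female` donors.
#' @param hotspot_fraction fraction of SNP intervals designated hot (per
#'   chromosome, rounded; the same intervals are hot in both sexes).
#' @param hotspot_multiplier intensity multiplier of hot intervals relative to
#'   the flat baseline, applied before renormalization to `map_length`.
#' @param panel_densities numeric vector of panel densities as fractions of
#'   the full SNP set (1 = full density). Lower-density panels keep an evenly
#'   spaced SNP subset, emulating lower-density chips.
#' @param panel_props mixing proportions over `panel_densities`, one per
#'   density; animals are assigned panels independently at these proportions.
#' @param error_rate per-genotype probability of replacing the observed allele
#'   count by a uniform draw from the other two values.
#' @param missing_rate per-genotype probability of setting the call missing.
#' @param prop_male_donors share of families whose donor parent is the sire.
#' @param seed integer random seed; mandatory, fully determines the output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 10L,
                       snps_per_chromosome = 200L,
                       chrom_length_bp = 1e8,
                       n_families = 100L,
                       breeds = c("Jersey", "BrownSwiss", "Ayrshire"),
                       map_length = c(male = 24.8, female = 22.5),
                       hotspot_fraction = 0.02,
                       hotspot_multiplier = 10,
                       panel_densities = 1,
                       panel_props = 1,
                       error_rate = 0,
                       missing_rate = 0,
                       prop_male_donors = 0.5,
                       seed) {
  if (missing(seed) || !is.finite(seed))
    stop("sim_config: 'seed' is mandatory")
  stopifnot(
    n_chromosomes >= 1, snps_per_chromosome >= 2,
    chrom_length_bp > snps_per_chromosome,
    n_families >= 0, length(breeds) >= 1, !anyDuplicated(breeds),
    length(panel_densities) == length(panel_props),
    all(panel_densities > 0 & panel_densities <= 1),
    all(panel_props >= 0), sum(panel_props) > 0
  )
  if (!all(c("male", "female") %in% names(map_length)))
    stop("map_length must be named with 'male' and 'female'")
  if (any(map_length <= 0))
    stop("map_length: expected crossovers per meiosis must be positive")
  for (r in c(hotspot_fraction, error_rate, missing_rate, prop_male_donors))
    if (r < 0 || r > 1) stop("rates and proportions must lie in [0, 1]")
  if (hotspot_multiplier <= 0) stop("hotspot_multiplier must be positive")
  n_int <- snps_per_chromosome - 1L
  if (hotspot_fraction > 0 && round(hotspot_fraction * n_int) < 1)
    stop("hotspot_fraction too small: no hot interval per chromosome; ",
         "use hotspot_fraction = 0 for a flat map")
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chrom_length_bp = chrom_length_bp,
    n_families = as.integer(n_families),
    breeds = breeds,
    map_length = map_length[c("male", "female")],
    hotspot_fraction = hotspot_fraction,
    hotspot_multiplier = hotspot_multiplier,
    panel_densities = panel_densities,
    panel_props = panel_props / sum(panel_props),
    error_rate = error_rate,
    missing_rate = missing_rate,
    prop_male_donors = prop_male_donors,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Build a ground-truth recombination map
#'
#' Draws SNP positions and lays down per-interval crossover intensities: a
#' flat baseline with a designated subset of hot intervals at
#' `hotspot_multiplier` times the baseline, then renormalizes each sex's
#' intensities so the genome-wide sum equals that sex's configured map length.
#' Intensities follow the package-wide interval convention: stored on the row
#' of the interval's right SNP, 0 on the first SNP of each chromosome.
#'
#' @param config a [sim_config()].
#' @return an object of class `true_map`: list with `snps` (data.table of
#'   name/chrom/bp), `intensity` (list of numeric vectors `male`, `female`),
#'   and `hot` (integer row indices of hot intervals).
#' @export
make_true_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$snps_per_chromosome
  snps <- rbindlist(lapply(seq_len(config$n_chromosomes), function(cc) {
    bp <- sort(sample.int(config$chrom_length_bp, m))
    data.table(name = sprintf("snp%d_%d", cc, seq_len(m)),
               chrom = cc, bp = bp)
  }))
  validate_snps(snps)
  first <- chrom_first(snps)
  base <- as.numeric(!first)            # flat baseline, one unit per interval
  hot <- integer(0)
  if (config$hotspot_fraction > 0) {
    n_hot <- round(config$hotspot_fraction * (m - 1L))
    hot <- unlist(lapply(seq_len(config$n_chromosomes), function(cc) {
      rows <- which(snps$chrom == cc & !first)
      sort(rows[sample.int(length(rows), n_hot)])
    }))
    base[hot] <- base[hot] * config$hotspot_multiplier
  }
  intensity <- lapply(config$map_length, function(L) base / sum(base) * L)
  structure(list(snps = snps, intensity = intensity, hot = hot,
                 chrom_rows = split(seq_len(nrow(snps)), snps$chrom)),
            class = "true_map")
}

#' Simulate one meiosis from a phased parent
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the
#' chromosome's intensity sum (no interference); each crossover falls in an
#' interval with probability proportional to its intensity and uniformly in bp
#' within it. The gamete starts on either parental haplotype with probability
#' 1/2 and alternates at each crossover.
#'
#' @param hap_pair integer matrix with 2 rows (the parent's two haplotypes,
#'   alleles 0/1) and one column per SNP of `true_map`.
#' @param true_map a [make_true_map()] result.
#' @param sex `"male"` or `"female"`; selects the intensity vector.
#' @return list with `gamete` (integer allele vector) and `xo` (data.table of
#'   truth crossovers: chrom, bp, interval row index).
#' @export
simulate_meiosis <- function(hap_pair, true_map, sex) {
  if (!sex %in% names(true_map$intensity))
    stop("sex '", sex, "' absent from true map")
  snps <- true_map$snps
  if (ncol(hap_pair) != nrow(snps))
    stop("haplotypes do not match true map SNP count")
  ints <- true_map$intensity[[sex]]
  n <- nrow(snps)
  chrom_rows <- true_map$chrom_rows %||%
    split(seq_len(n), snps$chrom)
  bp <- snps$bp
  gam <- integer(n)
  xo_int <- vector("list", length(chrom_rows))
  xo_bp <- vector("list", length(chrom_rows))
  xo_ch <- vector("list", length(chrom_rows))
  for (ci in seq_along(chrom_rows)) {
    rows <- chrom_rows[[ci]]
    lam <- sum(ints[rows])
    k <- if (lam > 0) rpois(1L, lam) else 0L
    start <- sample.int(2L, 1L)
    if (k > 0L) {
      iv <- rows[sample.int(length(rows), k, replace = TRUE,
                            prob = ints[rows])]
      pos <- runif(k, bp[iv - 1L], bp[iv])
      o <- order(pos)
      iv <- iv[o]; pos <- pos[o]
      cnt <- findInterval(bp[rows], pos)
      hap <- ((start - 1L + cnt) %% 2L) + 1L
      xo_int[[ci]] <- iv; xo_bp[[ci]] <- pos
      xo_ch[[ci]] <- rep.int(snps$chrom[rows[1L]], k)
    } else {
      hap <- rep.int(start, length(rows))
    }
    gam[rows] <- hap_pair[cbind(hap, rows)]
  }
  list(gamete = gam,
       xo = data.table(chrom = as.integer(unlist(xo_ch)),
                       bp = as.numeric(unlist(xo_bp)),
                       interval = as.integer(unlist(xo_int))))
}

# founder: two haplotypes drawn from per-SNP allele frequencies
.founder_haps <- function(freq) {
  rbind(rbinom(length(freq), 1L, freq), rbinom(length(freq), 1L, freq))
}

#' Simulate a genotyped multi-breed cohort with known crossover truth
#'
#' Each family has five genotyped animals: grandsire and granddam (founders),
#' their offspring the donor parent, an unrelated founder mate, and one
#' offspring of donor x mate. Only the (offspring, donor) pair satisfies the
#' three-generation rule (genotyped offspring, parent and grandparent), so a
#' cohort yields exactly `n_families` analyzable meioses per breed. Founder
#' haplotypes are drawn from per-SNP allele frequencies uniform in
#' [0.05, 0.95]; genotypes are then reduced to panel subsets and corrupted by
#' the configured error and missing rates.
#'
#' @param config a [sim_config()].
#' @param true_map optional [make_true_map()] result to reuse; lets several
#'   cohorts (e.g. batches of families, or separate-sex cohorts) share one
#'   genome and intensity surface. When supplied, `config$seed` drives only
#'   the family-level randomness.
#' @param id_prefix string prepended to every animal id; keeps ids unique
#'   when batched cohorts are combined downstream.
#' @return list with `cohort` (a [new_cohort()] object), `truth` (data.table
#'   of all simulated crossovers: meiosis, donor, offspring, sex, chrom, bp,
#'   interval), `meioses` (data.table of all simulated transmissions with an
#'   `analyzed` flag marking donor-to-offspring meioses extractable as
#'   three-generation families), `true_map`, and `freq` (the founder allele
#'   frequencies drawn per SNP).
#' @export
simulate_cohort <- function(config, true_map = NULL, id_prefix = "") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families < 1L) stop("simulate_cohort: zero families requested")
  if (is.null(true_map)) {
    tmap <- make_true_map(config)        # seeds the RNG from config$seed
  } else {
    stopifnot(inherits(true_map, "true_map"))
    if (nrow(true_map$snps) !=
        config$n_chromosomes * config$snps_per_chromosome)
      stop("supplied true_map does not match the configured genome size")
    tmap <- true_map
    set.seed(config$seed)
  }
  snps <- tmap$snps
  n_snp <- nrow(snps)
  freq <- runif(n_snp, 0.05, 0.95)
  nb <- length(config$breeds)
  nf <- config$n_families
  n_animals <- 5L * nf * nb
  n_fam_tot <- nb * nf
  geno <- matrix(-1L, n_animals, n_snp)
  ped_id <- character(n_animals); ped_sire <- character(n_animals)
  ped_dam <- character(n_animals); ped_sex <- character(n_animals)
  ped_breed <- character(n_animals)
  t_mei <- vector("list", n_fam_tot); t_don <- vector("list", n_fam_tot)
  t_off <- vector("list", n_fam_tot); t_sex <- vector("list", n_fam_tot)
  t_xo <- vector("list", n_fam_tot)
  m_don <- vector("list", n_fam_tot); m_off <- vector("list", n_fam_tot)
  m_sex <- vector("list", n_fam_tot); m_breed <- vector("list", n_fam_tot)
  ids <- character(n_animals)
  n_male <- round(config$prop_male_donors * nf)
  row0 <- 0L
  fam_i <- 0L
  for (b in config$breeds) {
    for (i in seq_len(nf)) {
      fam_i <- fam_i + 1L
      donor_sex <- if (i <= n_male) "male" else "female"
      mate_sex <- if (donor_sex == "male") "female" else "male"
      tag <- sprintf("%s%s_F%05d", id_prefix, b, i)
      id <- paste0(tag, c("_GS", "_GD", "_MT", "_P", "_O"))
      gs <- .founder_haps(freq); gd <- .founder_haps(freq)
      mt <- .founder_haps(freq)
      m1 <- simulate_meiosis(gs, tmap, "male")
      m2 <- simulate_meiosis(gd, tmap, "female")
      p_hap <- rbind(m1$gamete, m2$gamete)  # row 1 paternal, row 2 maternal
      m3 <- simulate_meiosis(p_hap, tmap, donor_sex)
      m4 <- simulate_meiosis(mt, tmap, mate_sex)
      geno[row0 + 1L, ] <- gs[1L, ] + gs[2L, ]
      geno[row0 + 2L, ] <- gd[1L, ] + gd[2L, ]
      geno[row0 + 3L, ] <- mt[1L, ] + mt[2L, ]
      geno[row0 + 4L, ] <- p_hap[1L, ] + p_hap[2L, ]
      geno[row0 + 5L, ] <- m3$gamete + m4$gamete
      ids[row0 + (1:5)] <- id
      sire_o <- if (donor_sex == "male") id[4L] else id[3L]
      dam_o <- if (donor_sex == "male") id[3L] else id[4L]
      rr <- row0 + (1:5)
      ped_id[rr] <- id
      ped_sire[rr] <- c(NA, NA, NA, id[1L], sire_o)
      ped_dam[rr] <- c(NA, NA, NA, id[2L], dam_o)
      ped_sex[rr] <- c("male", "female", mate_sex, donor_sex, "male")
      ped_breed[rr] <- b
      dn <- c(id[1L], id[2L], id[4L], id[3L])
      ch <- c(id[4L], id[4L], id[5L], id[5L])
      sx <- c("male", "female", donor_sex, mate_sex)
      xos <- list(m1$xo, m2$xo, m3$xo, m4$xo)
      nx <- vapply(xos, nrow, 0L)
      t_mei[[fam_i]] <- rep.int(paste0(dn, ">", ch), nx)
      t_don[[fam_i]] <- rep.int(dn, nx)
      t_off[[fam_i]] <- rep.int(ch, nx)
      t_sex[[fam_i]] <- rep.int(sx, nx)
      t_xo[[fam_i]] <- xos
      m_don[[fam_i]] <- dn; m_off[[fam_i]] <- ch
      m_sex[[fam_i]] <- sx; m_breed[[fam_i]] <- rep.int(b, 4L)
      row0 <- row0 + 5L
    }
  }
  truth <- data.table(
    meiosis = unlist(t_mei), donor = unlist(t_don),
    offspring = unlist(t_off), sex = unlist(t_sex),
    rbindlist(unlist(t_xo, recursive = FALSE))
  )
  meioses <- data.table(
    meiosis = paste0(unlist(m_don), ">", unlist(m_off)),
    donor = unlist(m_don), offspring = unlist(m_off),
    sex = unlist(m_sex), breed = unlist(m_breed),
    analyzed = rep(c(FALSE, FALSE, TRUE, FALSE), n_fam_tot)
  )
  rownames(geno) <- ids
  colnames(geno) <- snps$name
  # panel reduction: evenly spaced SNP subsets per density class
  dens <- config$panel_densities
  panel_sets <- lapply(dens, function(f) {
    if (f >= 1) seq_len(n_snp)
    else unique(round(seq(1, n_snp, length.out = max(2, round(f * n_snp)))))
  })
  assign <- sample.int(length(dens), n_animals, replace = TRUE,
                       prob = config$panel_props)
  for (k in seq_along(dens)) {
    drop <- setdiff(seq_len(n_snp), panel_sets[[k]])
    if (length(drop)) geno[assign == k, drop] <- -1L
  }
  # symmetric genotyping error on typed calls, then missingness
  if (config$error_rate > 0) {
    typed <- which(geno >= 0L)
    hit <- typed[runif(length(typed)) < config$error_rate]
    if (length(hit)) {
      old <- geno[hit]
      shift <- 1L + (runif(length(hit)) < 0.5)      # +1 or +2 mod 3
      geno[hit] <- (old + shift) %% 3L
    }
  }
  if (config$missing_rate > 0) {
    typed <- which(geno >= 0L)
    geno[typed[runif(length(typed)) < config$missing_rate]] <- -1L
  }
  ped <- data.table(id = ped_id, sire = ped_sire, dam = ped_dam,
                    sex = ped_sex, breed = ped_breed)
  cohort <- new_cohort(ped, snps, geno)
  list(cohort = cohort, truth = truth, meioses = meioses, true_map = tmap,
       freq = freq)
}

#' Meiosis records at exact truth resolution
#'
#' Converts simulator truth crossovers into the per-meiosis record/mass tables
#' used downstream, with each crossover assigned wholly to its true SNP
#' interval. This bypasses detection and is the reference input for
#' statistical-calibration checks where detection-resolution effects (mass
#' spread over informative gaps) are deliberately excluded.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param meioses meioses table from [simulate_cohort()]; rows with
#'   `analyzed = TRUE` are kept, including zero-crossover meioses.
#' @return list with `records` and `masses` in the layout of
#'   [detect_crossovers()].
#' @export
meiosis_records_from_truth <- function(truth, meioses) {
  mm <- meioses[analyzed == TRUE]
  tt <- truth[meiosis %in% mm$meiosis]
  masses <- tt[, .(mass = as.numeric(.N)), by = .(meiosis, interval)]
  cnt <- masses[, .(n_xo = sum(mass)), by = meiosis]
  records <- merge(mm[, .(meiosis, offspring, donor, sex, breed)],
                   cnt, by = "meiosis", all.x = TRUE)
  records[is.na(n_xo), n_xo := 0]
  records[, `:=`(n_inf_donor = NA_integer_, n_inf_off = NA_integer_,
                 density = NA_integer_)]
  setkey(records, meiosis)
  list(records = records[], masses = masses)
}
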