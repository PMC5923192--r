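# build a donor phased pair + transmitted haplotype realizing a template
# pattern over a given set of informative sites
make_trace_input <- function(pattern, n_sites = NULL) {
  k <- nchar(pattern)
  n <- n_sites %||% (k + 2L)
  donor <- structure(list(h1 = rep(0L, n), h2 = rep(1L, n),
                          geno = rep(1L, n), mendel = integer(0)),
                     class = "phased_pair")
  sites <- seq_len(k) + 1L
  transmitted <- rep(NA_integer_, n)
  tm <- strsplit(pattern, "")[[1L]]
  transmitted[sites] <- ifelse(tm == "A", 0L, 1L)   # A matches h1
  list(donor = donor, sites = sites, transmitted = transmitted,
       chrom = rep(1L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("template switches are traced with run-length filtering", {
  # AABBB: one crossover between informative sites 2 and 3
  x <- make_trace_input("AABBB")
  tr <- trace_crossovers(x$transmitted, x$donor, x$sites, x$chrom,
                         min_support = 2L)
  expect_equal(nrow(tr$switches), 1L)
  expect_equal(tr$switches$a, x$sites[2])
  expect_equal(tr$switches$b, x$sites[3])
  # AABAA with support 2: isolated B masked, no crossover
  x <- make_trace_input("AABAA")
  tr <- trace_crossovers(x$transmitted, x$donor, x$sites, x$chrom,
                         min_support = 2L)
  expect_equal(nrow(tr$switches), 0L)
  expect_equal(tr$n_masked, 1L)
  # with support 1 the same pattern gives two crossovers
  tr1 <- trace_crossovers(x$transmitted, x$donor, x$sites, x$chrom,
                          min_support = 1L)
  expect_equal(nrow(tr1$switches), 2L)
  # unknown transmitted sites are skipped, not masked
  x <- make_trace_input("AAABBB")
  x$transmitted[x$sites[3]] <- NA_integer_
  tr <- trace_crossovers(x$transmitted, x$donor, x$sites, x$chrom, 2L)
  expect_equal(tr$n_used, 5L)
  expect_equal(tr$n_masked, 0L)
  expect_equal(nrow(tr$switches), 1L)
  expect_equal(tr$switches$a, x$sites[2])   # gap widens across the skip
  expect_equal(tr$switches$b, x$sites[4])
})

test_that("crossover mass is split evenly across spanned intervals", {
  m <- assign_crossover_mass(10L, 14L)
  expect_equal(m$interval, 11:14)
  expect_equal(m$mass, rep(0.25, 4))
  m1 <- assign_crossover_mass(3L, 4L)
  expect_equal(m1$interval, 4L)
  expect_equal(m1$mass, 1)
  expect_error(assign_crossover_mass(5L, 5L))
  # conservation over random spans
  set.seed(4)
  for (i in 1:20) {
    a <- sample.int(100, 1)
    b <- a + sample.int(30, 1)
    expect_equal(sum(assign_crossover_mass(a, b)$mass), 1)
  }
})

test_that("meiosis QC removes only counts strictly above the threshold", {
  rec <- data.table::data.table(
    meiosis = c("m1", "m2", "m3"), offspring = "o", donor = "d",
    sex = "male", breed = "X", n_xo = c(46, 45, 0),
    n_inf_donor = 10L, n_inf_off = 10L, density = 100L, n_masked = 0L)
  masses <- data.table::data.table(
    meiosis = c(rep("m1", 46), rep("m2", 45)),
    interval = 2L, mass = 1)
  out <- qc_filter_meioses(list(records = rec, masses = masses), qc_config())
  expect_setequal(out$records$meiosis, c("m2", "m3"))
  expect_equal(out$excluded$meiosis, "m1")
  expect_true(all(out$masses$meiosis == "m2"))
})

test_that("detected switches equal truth parity over surviving sites", {
  sim <- small_sim()
  co <- sim$cohort
  fams <- extract_families(co, density_threshold = 100)$families
  sire_of <- setNames(co$ped$sire, co$ped$id)
  dam_of <- setNames(co$ped$dam, co$ped$id)
  truth <- sim$truth
  set.seed(6)
  total_detected <- 0L
  for (i in sample.int(nrow(fams), 25)) {
    don <- fams$donor[i]; off <- fams$offspring[i]
    donor_pp <- phase_trio(co$geno[don, ], co$geno[sire_of[don], ],
                           co$geno[dam_of[don], ])
    off_pp <- phase_trio(co$geno[off, ], co$geno[sire_of[off], ],
                         co$geno[dam_of[off], ])
    transmitted <- if (fams$donor_sex[i] == "male") off_pp$h1 else off_pp$h2
    tr <- trace_crossovers(transmitted, donor_pp,
                           informative_sites(donor_pp), co$snps$chrom, 2L)
    tru <- truth[meiosis == paste0(don, ">", off)]
    # per gap between consecutive surviving informative sites, the detected
    # indicator must equal the parity of true crossovers inside the gap
    sites <- sort(tr$sites)
    odd <- integer(0); got <- integer(0)
    for (cc in unique(co$snps$chrom[sites])) {
      sc <- sites[co$snps$chrom[sites] == cc]
      if (length(sc) < 2L) next
      j <- seq_len(length(sc) - 1L)
      odd <- c(odd, vapply(j, function(jj)
        nrow(tru[chrom == cc & bp > co$snps$bp[sc[jj]] &
                   bp < co$snps$bp[sc[jj + 1L]]]) %% 2L, 0L))
      got <- c(got, vapply(j, function(jj)
        as.integer(any(tr$switches$a == sc[jj] &
                         tr$switches$b == sc[jj + 1L])), 0L))
    }
    expect_equal(got, odd)
    total_detected <- total_detected + nrow(tr$switches)
  }
  expect_gt(total_detected, 0L)
})

test_that("spurious crossover rate stays low under genotyping error", {
  cfg <- sim_config(n_chromosomes = 5, snps_per_chromosome = 600,
                    n_families = 120, breeds = "E", error_rate = 0.002,
                    hotspot_fraction = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  fams <- extract_families(sim$cohort, density_threshold = 1000)
  co <- sim$cohort
  snps <- co$snps
  truth <- sim$truth
  sire_of <- setNames(co$ped$sire, co$ped$id)
  dam_of <- setNames(co$ped$dam, co$ped$id)
  ff <- fams$families
  # a detected switch is spurious if no truth crossover of that meiosis lies
  # inside its flanking-site span
  n_spur <- 0L
  for (i in seq_len(nrow(ff))) {
    don <- ff$donor[i]; off <- ff$offspring[i]
    donor_pp <- phase_trio(co$geno[don, ], co$geno[sire_of[don], ],
                           co$geno[dam_of[don], ])
    off_pp <- phase_trio(co$geno[off, ], co$geno[sire_of[off], ],
                         co$geno[dam_of[off], ])
    transmitted <- if (ff$donor_sex[i] == "male") off_pp$h1 else off_pp$h2
    tr <- trace_crossovers(transmitted, donor_pp,
                           informative_sites(donor_pp), snps$chrom, 2L)
    tru <- truth[meiosis == paste0(don, ">", off)]
    for (j in seq_len(nrow(tr$switches))) {
      cc <- tr$switches$chrom[j]
      lo <- snps$bp[tr$switches$a[j]]; hi <- snps$bp[tr$switches$b[j]]
      if (!nrow(tru[chrom == cc & bp > lo & bp < hi])) n_spur <- n_spur + 1L
    }
  }
  expect_lt(n_spur / nrow(ff), 0.5)
})
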