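# Shared fixtures and small simulation utilities for the test suite.
# Everything is generated in code under fixed seeds.

library(data.table)

# hand-built rec_map on a single-breed toy genome
toy_recmap <- function(rate, chrom, bp, breed = "toy", sex = "male",
                       n_meioses = 1L) {
  snps <- data.table(name = sprintf("s%d", seq_along(bp)),
                     chrom = chrom, bp = bp)
  structure(list(breed = breed, sex = sex, n_meioses = n_meioses,
                 snps = snps, rate = rate),
            class = "rec_map")
}

# true map with hand-set intensities (bypasses make_true_map randomness)
toy_truemap <- function(male, female, chrom, bp) {
  snps <- data.table(name = sprintf("s%d", seq_along(bp)),
                     chrom = chrom, bp = bp)
  structure(list(snps = snps,
                 intensity = list(male = male, female = female),
                 hot = integer(0),
                 chrom_rows = split(seq_along(bp), chrom)),
            class = "true_map")
}

# simulate n meioses of truth crossovers from a true map (no genotypes, no
# detection): returns records/masses in the detect_crossovers layout, each
# crossover carried at exact single-interval resolution
sim_truth_meioses <- function(tmap, n, sex = "male", breed = "sim",
                              prefix = "m") {
  dummy <- matrix(0L, 2L, nrow(tmap$snps))
  mei <- vector("list", n)
  for (i in seq_len(n)) {
    xo <- simulate_meiosis(dummy, tmap, sex)$xo
    mei[[i]] <- if (nrow(xo)) data.table(meiosis = sprintf("%s%05d", prefix, i),
                                         interval = xo$interval)
    else NULL
  }
  ev <- rbindlist(mei)
  masses <- if (nrow(ev)) ev[, .(mass = as.numeric(.N)),
                             by = .(meiosis, interval)]
  else data.table(meiosis = character(), interval = integer(),
                  mass = numeric())
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  cnt <- masses[, .(n_xo = sum(mass)), by = meiosis]
  records <- data.table(meiosis = ids, offspring = ids,
                        donor = paste0("d_", ids), sex = sex, breed = breed,
                        n_xo = 0)
  records[cnt, n_xo := i.n_xo, on = "meiosis"]
  records[, `:=`(n_inf_donor = NA_integer_, n_inf_off = NA_integer_,
                 density = NA_integer_)]
  list(records = records, masses = masses)
}

# cached small full-density error-free cohort shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chromosomes = 4, snps_per_chromosome = 400,
                        n_families = 120, breeds = c("B1", "B2"),
                        hotspot_fraction = 0, seed = 20260919)
      cache <<- c(simulate_cohort(cfg), list(config = cfg))
    }
    cache
  }
})
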