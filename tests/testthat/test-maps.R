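make_records <- function(ids, n_xo = 0, sex = "male", breed = "X") {
  data.table::data.table(
    meiosis = ids, offspring = ids, donor = paste0("d", ids), sex = sex,
    breed = breed, n_xo = n_xo, n_inf_donor = 10L, n_inf_off = 10L,
    density = 1000L, n_masked = 0L)
}

test_that("map rates are mean crossover mass per meiosis", {
  snps <- data.table::data.table(name = paste0("s", 1:10), chrom = 1L,
                                 bp = (1:10) * 1000L)
  rec <- make_records(c("m1", "m2"), n_xo = c(1, 0))
  masses <- data.table::data.table(meiosis = "m1", interval = 7L, mass = 1)
  mp <- build_recmap(rec, masses, snps)
  expect_equal(mp$rate[7], 0.5)
  expect_equal(sum(mp$rate), 0.5)
  expect_equal(mp$rate[-7], rep(0, 9))
  expect_equal(map_length(mp), mean(rec$n_xo))
  expect_error(build_recmap(rec[0], masses, snps), "no meioses")
})

test_that("maps merge as meiosis-count-weighted averages", {
  set.seed(12)
  snps <- data.table::data.table(name = paste0("s", 1:50), chrom = 1L,
                                 bp = sort(sample.int(1e6, 50)))
  ids1 <- paste0("a", 1:30); ids2 <- paste0("b", 1:70)
  mk_masses <- function(ids) {
    data.table::rbindlist(lapply(ids, function(m) {
      k <- rpois(1, 2)
      if (!k) return(NULL)
      data.table::data.table(meiosis = m,
                             interval = sample(2:50, k, replace = TRUE),
                             mass = 1)
    }))
  }
  ms1 <- mk_masses(ids1); ms2 <- mk_masses(ids2)
  r1 <- make_records(ids1); r2 <- make_records(ids2)
  m1 <- build_recmap(r1, ms1, snps)
  m2 <- build_recmap(r2, ms2, snps)
  mu <- build_recmap(rbind(r1, r2), rbind(ms1, ms2), snps)
  expect_equal(mu$rate, (30 * m1$rate + 70 * m2$rate) / 100)
  # conservation: rate sum x meioses = total mass
  expect_equal(sum(mu$rate) * mu$n_meioses, sum(ms1$mass) + sum(ms2$mass))
})

test_that("map correlation equals the covariance formula and handles edge cases", {
  set.seed(14)
  n <- 1000
  snps <- data.table::data.table(name = paste0("s", 1:(n + 1)), chrom = 1L,
                                 bp = seq_len(n + 1) * 100L)
  a <- toy_recmap(c(0, runif(n)), rep(1L, n + 1), snps$bp)
  b <- toy_recmap(c(0, runif(n)), rep(1L, n + 1), snps$bp)
  # oracle: direct covariance-formula computation over interval rows
  x <- a$rate[-1]; y <- b$rate[-1]
  r_direct <- mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  expect_equal(map_correlation(a, b), r_direct, tolerance = 1e-12)
  expect_equal(map_correlation(a, a), 1)
  flat <- toy_recmap(c(0, rep(0.01, n)), rep(1L, n + 1), snps$bp)
  expect_warning(r0 <- map_correlation(a, flat), "zero-variance")
  expect_true(is.na(r0))
})

test_that("equal-sample correlations are deterministic and exchangeable", {
  set.seed(15)
  tm <- make_true_map(sim_config(n_chromosomes = 2, snps_per_chromosome = 150,
                                 hotspot_fraction = 0.05,
                                 hotspot_multiplier = 20, seed = 99))
  set.seed(100)
  dets <- list(P1 = sim_truth_meioses(tm, 600, prefix = "p"),
               P2 = sim_truth_meioses(tm, 800, prefix = "q"),
               P3 = sim_truth_meioses(tm, 700, prefix = "r"))
  set.seed(200)
  e1 <- equal_sample_correlation(dets, tm$snps, k = 400, reps = 40)
  set.seed(200)
  e2 <- equal_sample_correlation(dets, tm$snps, k = 400, reps = 40)
  expect_identical(e1$mean_cor, e2$mean_cor)
  off <- e1$mean_cor[upper.tri(e1$mean_cor)]
  # same underlying truth: mean correlations mutually close
  expect_lt(max(off) - min(off), 0.05)
  expect_error(equal_sample_correlation(dets, tm$snps, k = 700), "exceeds")

  # populations with different hotspot placements correlate lower
  tm2 <- make_true_map(sim_config(n_chromosomes = 2,
                                  snps_per_chromosome = 150,
                                  hotspot_fraction = 0.05,
                                  hotspot_multiplier = 20, seed = 77))
  expect_false(identical(tm2$hot, tm$hot))
  set.seed(300)
  dets2 <- list(A = sim_truth_meioses(tm, 600, prefix = "a"),
                B = sim_truth_meioses(tm2, 600, prefix = "b"))
  set.seed(301)
  e_diff <- equal_sample_correlation(dets2, tm$snps, k = 400, reps = 40)
  expect_lt(e_diff$mean_cor["A", "B"], min(off))
})

test_that("position profiles respond to constructed enrichment", {
  n <- 200
  bp <- rep(seq(5e5, 1e8, length.out = n / 2), 2)
  snps_bp <- as.integer(bp)
  chrom <- rep(1:2, each = n / 2)
  w <- c(0, diff(snps_bp))
  first <- c(TRUE, chrom[-1] != chrom[-n])
  w[first] <- 0
  # flat per-Mb rate: fitted curve constant within 1%
  flat <- toy_recmap(w * 1e-8, chrom, snps_bp)
  pr <- position_profile(flat, spar = 0.8)
  expect_true(all(pr$profile$position >= 0 & pr$profile$position <= 1))
  expect_lt(diff(range(pr$profile$rate)) / mean(pr$profile$rate), 0.01)
  # telomere-enriched map: curve at 0.95 above curve at 0.5
  relpos <- ave(seq_along(bp), chrom, FUN = function(i) i / max(i))
  enr <- toy_recmap(w * 1e-8 * (1 + 9 * (relpos > 0.9)), chrom, snps_bp)
  pe <- position_profile(enr, spar = 0.6)
  at <- function(p, x) p$profile$rate[which.min(abs(p$profile$position - x))]
  expect_gt(at(pe, 0.95), at(pe, 0.5))
  expect_error(position_profile(flat, spar = 1.5), "spar")
})
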