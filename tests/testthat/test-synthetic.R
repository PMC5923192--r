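test_that("true map normalizes to the configured sex-specific lengths", {
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 50,
                    hotspot_fraction = 0, seed = 1)
  tm <- make_true_map(cfg)
  expect_equal(sum(tm$intensity$male), 24.8)
  expect_equal(sum(tm$intensity$female), 22.5)
  expect_true(all(tm$intensity$male >= 0))
  # chromosome-first rows carry no interval intensity
  first <- c(TRUE, tm$snps$chrom[-1] != tm$snps$chrom[-nrow(tm$snps)])
  expect_true(all(tm$intensity$male[first] == 0))
  # positions strictly increasing within chromosome
  expect_true(all(tapply(tm$snps$bp, tm$snps$chrom,
                         function(x) all(diff(x) > 0))))
})

test_that("multiplier 1 gives the same map as no hotspots", {
  cfg0 <- sim_config(n_chromosomes = 2, snps_per_chromosome = 101,
                     hotspot_fraction = 0, seed = 5)
  cfg1 <- sim_config(n_chromosomes = 2, snps_per_chromosome = 101,
                     hotspot_fraction = 0.1, hotspot_multiplier = 1, seed = 5)
  tm0 <- make_true_map(cfg0)
  tm1 <- make_true_map(cfg1)
  expect_equal(tm1$snps, tm0$snps)
  expect_equal(tm1$intensity, tm0$intensity)
})

test_that("hot intervals carry the closed-form share of total intensity", {
  # 10% hot at 40x: share = 0.1*40 / (0.1*40 + 0.9)
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 101,
                    hotspot_fraction = 0.1, hotspot_multiplier = 40, seed = 2)
  tm <- make_true_map(cfg)
  share <- sum(tm$intensity$male[tm$hot]) / sum(tm$intensity$male)
  expect_equal(share, (0.1 * 40) / (0.1 * 40 + 0.9), tolerance = 1e-12)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(seed = 1, map_length = c(male = -1, female = 22)),
               "positive")
  expect_error(sim_config(seed = 1, error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, snps_per_chromosome = 2000,
                          hotspot_fraction = 1e-5), "hotspot_fraction")
})

test_that("zero-intensity meiosis returns an unmodified parental haplotype", {
  tm <- toy_truemap(male = numeric(10), female = numeric(10),
                    chrom = rep(1L, 10), bp = seq(10, 100, 10))
  haps <- rbind(rep(0L, 10), rep(1L, 10))
  set.seed(3)
  out <- simulate_meiosis(haps, tm, "male")
  expect_equal(nrow(out$xo), 0L)
  expect_true(all(out$gamete == 0L) || all(out$gamete == 1L))
  expect_error(simulate_meiosis(haps, tm, "hermaphrodite"), "absent")
})

test_that("crossover counts follow the Poisson model", {
  # single interval with intensity 0.5: P(>=1 crossover) = 1 - exp(-0.5)
  tm <- toy_truemap(male = c(0, 0.5), female = c(0, 0.5),
                    chrom = c(1L, 1L), bp = c(1, 1e6))
  haps <- rbind(0L:1L, 1L:0L)
  set.seed(11)
  n <- 4000
  counts <- vapply(seq_len(n),
                   function(i) nrow(simulate_meiosis(haps, tm, "male")$xo), 0L)
  p_hat <- mean(counts >= 1)
  p_true <- 1 - exp(-0.5)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  expect_lt(abs(mean(counts) - 0.5), 3 * sqrt(0.5 / n))
  # truth positions lie strictly between the flanking SNPs
  xo <- simulate_meiosis(haps, tm, "male")$xo
  if (nrow(xo)) expect_true(all(xo$bp > 1 & xo$bp < 1e6))
})

test_that("genome-wide truth count matches the configured map length", {
  sim <- small_sim()
  truth_analyzed <- sim$truth[sim$meioses[analyzed == TRUE],
                              on = "meiosis", nomatch = 0]
  per <- truth_analyzed[, .N, by = .(meiosis, sex)]
  # include zero-crossover meioses
  all_mei <- sim$meioses[analyzed == TRUE]
  per <- merge(all_mei[, .(meiosis, sex)], per[, .(meiosis, N)],
               by = "meiosis", all.x = TRUE)
  per[is.na(N), N := 0L]
  for (sx in c("male", "female")) {
    mu <- mean(per[sex == sx, N])
    L <- sim$config$map_length[[sx]]
    n <- nrow(per[sex == sx])
    expect_lt(abs(mu - L), 3 * sqrt(L / n))
  }
})

test_that("cohort simulation is seed-deterministic", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 60,
                    n_families = 8, breeds = "X", error_rate = 0.01,
                    missing_rate = 0.05, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$geno, b$cohort$geno)
  expect_equal(a$truth, b$truth)
  expect_equal(a$cohort$ped, b$cohort$ped)
})

test_that("founder allele frequencies track the drawn frequencies", {
  sim <- small_sim()
  founders <- sim$cohort$ped[is.na(sire) & is.na(dam), id]
  G <- sim$cohort$geno[founders, ]
  # each founder genotype is Binomial(2, p); pooled mean within sampling bounds
  p_hat <- colMeans(G) / 2
  p <- sim$freq
  n <- length(founders)
  se <- sqrt(p * (1 - p) / (2 * n))
  expect_gt(mean(abs(p_hat - p) <= 4 * se), 0.99)
})

test_that("error and missing rates degrade genotypes at the configured rates", {
  cfg0 <- sim_config(n_chromosomes = 2, snps_per_chromosome = 150,
                     n_families = 40, breeds = "X", seed = 13)
  cfg1 <- sim_config(n_chromosomes = 2, snps_per_chromosome = 150,
                     n_families = 40, breeds = "X", error_rate = 0.02,
                     missing_rate = 0.1, seed = 13)
  g0 <- simulate_cohort(cfg0)$cohort$geno
  g1 <- simulate_cohort(cfg1)$cohort$geno
  n <- length(g0)
  miss <- mean(g1 == -1L)
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  typed <- g1 != -1L
  err <- mean(g1[typed] != g0[typed])
  expect_lt(abs(err - 0.02), 4 * sqrt(0.02 * 0.98 / sum(typed)))
})

test_that("truth-resolution records conserve crossover counts", {
  sim <- small_sim()
  tr <- meiosis_records_from_truth(sim$truth, sim$meioses)
  expect_equal(sum(tr$records$n_xo), nrow(sim$truth[
    meiosis %in% sim$meioses[analyzed == TRUE, meiosis]]))
  expect_equal(sum(tr$masses$mass), sum(tr$records$n_xo))
  expect_equal(nrow(tr$records), sum(sim$meioses$analyzed))
})
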