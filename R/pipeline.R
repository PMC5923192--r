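#' Run the full recombination analysis pipeline
#'
#' Orchestrates, in order: cohort input (read from files or simulate),
#' three-generation family extraction, crossover detection and QC,
#' breed/sex-specific map construction (high-density meioses only), hotspot
#' calling and sharing, pairwise per-interval chi-square comparisons,
#' phenotype derivation, and the mixed-model GWAS. Every stage writes its
#' outputs (TSV with a commented header recording version and seed) before
#' the next starts; a run log records the counts at every filter. Reruns with
#' the same configuration are deterministic.
#'
#' @param config configuration list or path to a YAML file. Recognized keys:
#'   `seed` (mandatory), `out_dir` (mandatory); either `simulate` (a list of
#'   [sim_config()] arguments) or `input` (list with `pedigree`, `snps`,
#'   `genotypes` paths); `density_threshold` (default 50000), `qc` (list of
#'   [qc_config()] arguments), `hotspot_multiplier` (default 2.5),
#'   `alpha_compare`, `alpha_gwas` (default 0.05), `breeds` (optional breed
#'   selection), `profile_spar` (optional), `equal_sample` (optional list
#'   with `k`, `reps`), `gwas_min_n` (default 30), `gwas_kinship`
#'   (`"grm"`, the default, or `"pedigree"` for the A-matrix).
#' @param last_stage run stages up to this one: one of `"families"`,
#'   `"detect"`, `"maps"`, `"hotspots"`, `"compare"`, `"pheno"`, `"gwas"`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, last_stage = "gwas") {
  stages <- c("families", "detect", "maps", "hotspots", "compare",
              "pheno", "gwas")
  last <- match.arg(last_stage, stages)
  want <- function(st) match(st, stages) <= match(last, stages)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config: 'seed' is mandatory")
  if (is.null(cfg$out_dir)) stop("config: 'out_dir' is mandatory")
  seed <- as.integer(cfg$seed)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pedrec %s | seed=%d", as.character(utils::packageVersion("pedrec")),
       seed)
  hdr <- sprintf("# pedrec %s seed=%d",
                 as.character(utils::packageVersion("pedrec")), seed)
  wtsv <- function(x, name) {
    path <- file.path(out, name)
    writeLines(hdr, path)
    fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
    path
  }
  res <- list()

  # --- cohort ---------------------------------------------------------------
  set.seed(seed)
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
    sim <- simulate_cohort(sc)
    cohort <- sim$cohort
    res$sim <- sim
    write_cohort(cohort, file.path(out, "cohort"))
    wtsv(sim$truth, "truth.tsv")
    logf("simulated cohort: %d animals, %d SNPs, %d breeds",
         nrow(cohort$geno), nrow(cohort$snps), length(sc$breeds))
  } else if (!is.null(cfg$input)) {
    cohort <- read_cohort(cfg$input$pedigree, cfg$input$snps,
                          cfg$input$genotypes)
    logf("read cohort: %d animals, %d SNPs", nrow(cohort$geno),
         nrow(cohort$snps))
  } else stop("config: provide either 'simulate' or 'input'")
  if (!is.null(cfg$breeds)) {
    keep <- cohort$ped$breed %in% cfg$breeds
    cohort <- new_cohort(cohort$ped[keep],
                         cohort$snps,
                         cohort$geno[rownames(cohort$geno) %in%
                                       cohort$ped$id[keep], , drop = FALSE])
    logf("breed selection: kept %s", paste(cfg$breeds, collapse = ", "))
  }
  res$cohort <- cohort

  # --- families -------------------------------------------------------------
  thr <- cfg$density_threshold %||% 50000
  fams <- extract_families(cohort, density_threshold = thr)
  wtsv(fams$families, "families.tsv")
  wtsv(fams$summary, "family_summary.tsv")
  logf("families: %d (threshold %d typed markers; %d high-density)",
       nrow(fams$families), as.integer(thr),
       sum(fams$families$density_class == "ge"))
  res$families <- fams
  if (!want("detect")) return(invisible(res))

  # --- detect + QC ----------------------------------------------------------
  qc <- do.call(qc_config, cfg$qc %||% list())
  det <- detect_crossovers(cohort, fams$families, qc)
  logf("detect: %d meioses traced, %d families dropped (Mendelian errors)",
       nrow(det$records), nrow(det$dropped))
  det <- qc_filter_meioses(det, qc)
  logf("qc: %d meioses removed with > %d crossovers; %d retained",
       nrow(det$excluded), qc$max_crossovers, nrow(det$records))
  wtsv(det$records, "meioses.tsv")
  wtsv(det$masses, "crossover_masses.tsv")
  if (nrow(det$excluded)) wtsv(det$excluded, "qc_excluded.tsv")
  res$detection <- det
  if (!want("maps")) return(invisible(res))

  # --- maps (high-density meioses only) -------------------------------------
  hi <- fams$families[density_class == "ge",
                      paste0(donor, ">", offspring)]
  rec_hi <- det$records[meiosis %in% hi]
  groups <- unique(rec_hi[, .(breed, sex)])
  setorder(groups, breed, sex)
  maps <- list()
  for (gi in seq_len(nrow(groups))) {
    mp <- build_recmap(rec_hi, det$masses, cohort$snps,
                       breed = groups$breed[gi], sex = groups$sex[gi])
    maps[[paste(groups$breed[gi], groups$sex[gi], sep = "_")]] <- mp
    logf("map %s_%s: %d meioses, length %.3f", groups$breed[gi],
         groups$sex[gi], mp$n_meioses, map_length(mp))
  }
  write_recmap(maps, file.path(out, "recombination_maps.tsv"))
  if (length(maps) >= 2L) {
    cm <- outer(seq_along(maps), seq_along(maps),
                Vectorize(function(i, j)
                  if (i == j) 1 else
                    suppressWarnings(map_correlation(maps[[i]], maps[[j]]))))
    dimnames(cm) <- list(names(maps), names(maps))
    wtsv(data.table(map = rownames(cm), cm), "map_correlations.tsv")
  }
  prof <- rbindlist(lapply(names(maps), function(nm) {
    pr <- position_profile(maps[[nm]], spar = cfg$profile_spar)
    data.table(map = nm, pr$profile)
  }))
  wtsv(prof, "position_profiles.tsv")
  if (!is.null(cfg$equal_sample) && length(maps) >= 2L) {
    dets <- lapply(split(rec_hi, rec_hi$breed), function(rr)
      list(records = rr, masses = det$masses[meiosis %in% rr$meiosis]))
    es <- equal_sample_correlation(dets, cohort$snps,
                                   k = cfg$equal_sample$k,
                                   reps = cfg$equal_sample$reps %||% 1000L)
    wtsv(data.table(breed = rownames(es$mean_cor), es$mean_cor),
         "equal_sample_correlations.tsv")
  }
  res$maps <- maps
  if (!want("hotspots")) return(invisible(res))

  # --- hotspots -------------------------------------------------------------
  crit <- hotspot_criteria(cfg$hotspot_multiplier %||% 2.5)
  hs <- lapply(maps, call_hotspots, criteria = crit)
  hs_tab <- rbindlist(lapply(hs, function(h)
    data.table(breed = h$breed, sex = h$sex,
               name = h$snps$name[h$intervals],
               chrom = h$snps$chrom[h$intervals],
               bp = h$snps$bp[h$intervals],
               threshold = h$threshold)))
  wtsv(hs_tab, "hotspots.tsv")
  for (sx in unique(groups$sex)) {
    sel <- hs[groups$sex == sx]
    if (length(sel) >= 2L) {
      names(sel) <- groups$breed[groups$sex == sx]
      sh <- hotspot_sharing(sel)
      wtsv(sh$partition[, .(sex = sx, pattern, count)],
           sprintf("hotspot_sharing_%s.tsv", sx))
      logf("hotspots (%s): all-shared %d of union %d", sx, sh$all_shared,
           sh$union_size)
    }
  }
  res$hotspots <- hs
  if (!want("compare")) return(invisible(res))

  # --- breed-pair comparisons within sex ------------------------------------
  cmp_out <- list()
  for (sx in unique(groups$sex)) {
    brs <- groups$breed[groups$sex == sx]
    if (length(brs) < 2L) next
    prs <- utils::combn(brs, 2L)
    for (ci in seq_len(ncol(prs))) {
      a <- prs[1L, ci]; b <- prs[2L, ci]
      da <- list(records = rec_hi[breed == a & sex == sx])
      db <- list(records = rec_hi[breed == b & sex == sx])
      da$masses <- det$masses[meiosis %in% da$records$meiosis]
      db$masses <- det$masses[meiosis %in% db$records$meiosis]
      sc <- interval_chisq_scan(da, db, cohort$snps,
                                alpha = cfg$alpha_compare %||% 0.05)
      nm <- sprintf("compare_%s_vs_%s_%s", a, b, sx)
      wtsv(sc, paste0(nm, ".tsv"))
      logf("%s: %d testable intervals, %d significant", nm,
           sum(sc$testable), sum(sc$sig))
      cmp_out[[nm]] <- sc
    }
  }
  res$compare <- cmp_out
  if (!want("pheno")) return(invisible(res))

  # --- phenotypes -----------------------------------------------------------
  phen_rate <- adjusted_recombination_rate(rec_hi)
  usage_tabs <- lapply(names(maps), function(nm) {
    h <- hs[[nm]]
    rr <- rec_hi[breed == h$breed & sex == h$sex]
    hotspot_usage(rr, det$masses[meiosis %in% rr$meiosis], h)
  })
  phen_usage <- rbindlist(usage_tabs)
  wtsv(phen_rate, "phenotype_rate.tsv")
  wtsv(phen_usage, "phenotype_usage.tsv")
  logf("phenotypes: %d animals (rate), %d animals (usage)",
       nrow(phen_rate), nrow(phen_usage))
  res$phenotypes <- list(rate = phen_rate, usage = phen_usage)
  if (!want("gwas")) return(invisible(res))

  # --- GWAS -----------------------------------------------------------------
  min_n <- cfg$gwas_min_n %||% 30L
  gw <- list()
  for (gi in seq_len(nrow(groups))) {
    b <- groups$breed[gi]; sx <- groups$sex[gi]
    for (ph in c("rate", "usage")) {
      tab <- res$phenotypes[[ph]][breed == b & sex == sx]
      tab <- tab[animal %in% rownames(cohort$geno)]
      if (nrow(tab) < min_n) {
        logf("gwas %s_%s_%s skipped: %d animals < %d", b, sx, ph,
             nrow(tab), min_n)
        next
      }
      G <- cohort$geno[tab$animal, , drop = FALSE]
      K <- if (identical(cfg$gwas_kinship, "pedigree"))
        pedigree_amatrix(cohort$ped)[tab$animal, tab$animal]
      else compute_grm(G)
      fit <- fit_null_reml(tab$value, K)
      scan <- snp_scan(tab$value, G, fit, snps = cohort$snps,
                       alpha = cfg$alpha_gwas %||% 0.05)
      nm <- sprintf("gwas_%s_%s_%s", b, sx, ph)
      wtsv(scan, paste0(nm, ".tsv"))
      logf("%s: n=%d h2=%.3f (%s), %d significant", nm, nrow(tab),
           fit$heritability, fit$status, sum(scan$sig, na.rm = TRUE))
      gw[[nm]] <- list(fit = fit, scan = scan)
    }
  }
  res$gwas <- gw
  invisible(res)
}
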