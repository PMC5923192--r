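#' Covariate-adjusted genome-wide recombination rate per animal
#'
#' Crossover counts depend on how well a meiosis can be observed: denser
#' panels and more informative markers reveal more crossovers. Counts are
#' therefore regressed (OLS, intercept included) on SNP density and the
#' informative-marker counts of donor and offspring; each animal's phenotype
#' is the mean residual over its meioses as donor. The adjustment is fitted
#' within breed x sex so population differences in mean count do not leak
#' into the residuals.
#'
#' @param records meiosis records from [detect_crossovers()] after QC,
#'   restricted to high-density families.
#' @param by grouping columns for the adjustment fit (default breed and sex).
#' @return data.table: animal, breed, sex, value (mean residual), n_meioses.
#' @export
adjusted_recombination_rate <- function(records, by = c("breed", "sex")) {
  records <- as.data.table(records)
  stopifnot(nrow(records) >= 2)
  records <- copy(records)
  records[, resid_xo := {
    covs <- c("density", "n_inf_donor", "n_inf_off")
    covs <- covs[vapply(covs, function(v) !anyNA(.SD[[v]]), TRUE)]
    f <- if (length(covs)) stats::reformulate(covs, "n_xo") else n_xo ~ 1
    fit <- lm(f, data = .SD)
    if (anyNA(coef(fit)))
      warning("constant or collinear covariates dropped in group ",
              paste(unlist(.BY), collapse = "/"), call. = FALSE)
    residuals(fit)
  }, by = by]
  records[, .(value = mean(resid_xo), n_meioses = .N),
          by = .(animal = donor, breed, sex)]
}

#' Hotspot-usage phenotype per animal
#'
#' Per meiosis, usage is the fraction of crossover mass falling in hotspot
#' intervals; meioses without crossovers carry no usage value (0/0). The
#' phenotype is the mean usage over an animal's informative meioses; animals
#' with only crossover-free meioses get no record.
#'
#' @param records,masses meiosis tables from [detect_crossovers()] after QC.
#' @param hotspots a [call_hotspots()] result from the matching breed-sex map.
#' @return data.table: animal, breed, sex, value (mean usage in `[0, 1]`),
#'   n_meioses (meioses with at least one crossover).
#' @export
hotspot_usage <- function(records, masses, hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  records <- as.data.table(records)
  masses <- as.data.table(masses)
  per_mei <- masses[, .(total = sum(mass),
                        hot = sum(mass[interval %in% hotspots$intervals])),
                    by = meiosis]
  per_mei <- per_mei[total > 0]
  per_mei[, usage := hot / total]
  merged <- merge(per_mei, records[, .(meiosis, donor, breed, sex)],
                  by = "meiosis")
  merged[, .(value = mean(usage), n_meioses = .N),
         by = .(animal = donor, breed, sex)]
}
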