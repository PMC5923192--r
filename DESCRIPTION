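Package: pedrec
Title: Pedigree-Based Recombination Maps, Hotspots and GWAS from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers in genotyped three-generation
    pedigrees by Mendelian trio phasing and haplotype tracing, builds
    breed- and sex-specific recombination maps on SNP-interval resolution,
    calls recombination hotspot regions (mean + 2.5 SD rule), compares
    per-interval rates between populations with chi-square scans, derives
    covariate-adjusted genome-wide recombination rate and hotspot-usage
    phenotypes, and runs a linear mixed model association scan with a
    genomic relationship matrix and eigen-rotated REML. Includes a
    simulator of genotyped multi-generation cohorts with known
    sex-specific crossover truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
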