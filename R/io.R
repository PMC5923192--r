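#' Construct and validate a cohort
#'
#' A cohort bundles a pedigree, an ordered SNP table and a genotype matrix.
#' Parents absent from the pedigree (or recorded as `0`/`NA`) are founders.
#'
#' @param ped data.frame/data.table with columns `id`, `sire`, `dam`, `sex`
#'   (`"male"`/`"female"`), `breed`. `NA` or `"0"` parent means unknown.
#' @param snps data.frame/data.table with `name`, `chrom`, `bp`, in genome
#'   order, positions strictly increasing within chromosome.
#' @param geno integer matrix, animals x SNPs, allele counts 0/1/2 with -1
#'   for missing; rownames are animal ids, colnames SNP names.
#' @return object of class `cohort`: list(ped, snps, geno, panel) where
#'   `panel` is the per-animal typed-marker count (the panel density label).
#' @export
new_cohort <- function(ped, snps, geno) {
  ped <- as.data.table(ped)
  snps <- as.data.table(snps)
  stopifnot(all(c("id", "sire", "dam", "sex", "breed") %in% names(ped)))
  ped[sire == "0", sire := NA_character_]
  ped[dam == "0", dam := NA_character_]
  if (anyDuplicated(ped$id)) stop("duplicated animal id in pedigree")
  if (!all(ped$sex %in% c("male", "female")))
    stop("pedigree sex must be 'male' or 'female'")
  validate_snps(snps)
  if (!is.matrix(geno)) stop("geno must be a matrix")
  if (storage.mode(geno) != "integer") storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("geno must carry animal ids as rownames and SNP names as colnames")
  if (ncol(geno) != nrow(snps) || !identical(colnames(geno), snps$name))
    stop("genotype columns do not match the SNP table (",
         ncol(geno), " vs ", nrow(snps), " SNPs)")
  missing_ids <- setdiff(rownames(geno), ped$id)
  if (length(missing_ids))
    stop("genotyped animal absent from pedigree: ", missing_ids[1L])
  # validate values and count typed markers in column blocks to keep the
  # peak allocation small on large matrices
  panel <- numeric(nrow(geno))
  blocks <- split(seq_len(ncol(geno)),
                  ceiling(seq_len(ncol(geno)) / 2000L))
  for (blk in blocks) {
    g <- geno[, blk, drop = FALSE]
    bad <- which(is.na(g) | g < -1L | g > 2L)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(g))
      stop("illegal genotype value ", g[bad[1L]], " at row ", rc[1L],
           " (", rownames(geno)[rc[1L]], "), column ", blk[rc[2L]],
           " (", colnames(geno)[blk[rc[2L]]], ")")
    }
    panel <- panel + rowSums(g >= 0L)
  }
  names(panel) <- rownames(geno)
  structure(list(ped = ped, snps = snps, geno = geno, panel = panel),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$ped), "animals in pedigree,",
      nrow(x$geno), "genotyped,", nrow(x$snps), "SNPs on",
      length(unique(x$snps$chrom)), "chromosomes\n")
  cat("breeds:", paste(sort(unique(x$ped$breed)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes three files into `dir`: `pedigree.fam` (6-column FAM dialect:
#' family = breed, id, sire, dam, sex 1/2, phenotype placeholder -9, unknown
#' parents as 0), `snps.tsv` (name, chrom, bp) and `genotypes.tsv` (one row
#' per animal, first column `id`, then one 0/1/2/-1 column per SNP).
#'
#' @param cohort a [new_cohort()] object.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written (named character vector).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.fam"),
             snps = file.path(dir, "snps.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"))
  fam <- cohort$ped[, .(family = breed, id,
                        sire = fifelse(is.na(sire), "0", sire),
                        dam = fifelse(is.na(dam), "0", dam),
                        sex = fifelse(sex == "male", 1L, 2L),
                        phenotype = -9L)]
  fwrite(fam, paths["pedigree"], sep = "\t", col.names = FALSE)
  fwrite(cohort$snps, paths["snps"], sep = "\t")
  gt <- as.data.table(cohort$geno, keep.rownames = "id")
  fwrite(gt, paths["genotypes"], sep = "\t")
  invisible(paths)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]: validates mutual consistency of the three
#' files and rebuilds the `cohort` object. Unknown parents (`0`) become
#' founders.
#'
#' @param pedigree path to the 6-column FAM-dialect pedigree.
#' @param snps path to the SNP metadata TSV (name, chrom, bp).
#' @param genotypes path to the genotype matrix TSV (id + one column per SNP).
#' @return a `cohort` object.
#' @export
read_cohort <- function(pedigree, snps, genotypes) {
  for (f in c(pedigree, snps, genotypes))
    if (!file.exists(f)) stop("file not found: ", f)
  fam <- fread(pedigree, header = FALSE, sep = "\t",
               colClasses = list(character = 1:4),
               col.names = c("family", "id", "sire", "dam", "sex",
                             "phenotype"))
  snp_dt <- fread(snps, sep = "\t")
  gt <- fread(genotypes, sep = "\t")
  if (names(gt)[1L] != "id") stop("genotype file must start with an 'id' column")
  geno <- as.matrix(gt[, -1L])
  rownames(geno) <- gt$id
  ped <- fam[, .(id, sire, dam,
                 sex = fifelse(sex == 1L, "male", "female"),
                 breed = family)]
  new_cohort(ped, snp_dt, geno)
}

#' Write recombination maps in the standard map-file layout
#'
#' One row per SNP in genome order with columns: SNP name, chromosome, bp,
#' then one rate column per map in the order given. The rate on each row is
#' the expected crossovers per meiosis in the interval between the current
#' and the preceding SNP; the first SNP of each chromosome carries 0.
#'
#' @param maps list of [build_recmap()] objects sharing one SNP table.
#' @param path output TSV path.
#' @param col_names optional column names for the rate columns; default
#'   `<breed>_<sex>` taken from each map.
#' @return invisibly, `path`.
#' @export
write_recmap <- function(maps, path, col_names = NULL) {
  stopifnot(length(maps) >= 1)
  for (m in maps) {
    stopifnot(inherits(m, "rec_map"))
    if (!same_snps(m$snps, maps[[1L]]$snps))
      stop("maps do not share the same SNP set")
  }
  if (is.null(col_names))
    col_names <- vapply(maps, function(m) paste(m$breed, m$sex, sep = "_"), "")
  if (anyDuplicated(col_names)) stop("duplicate rate column names")
  out <- copy(maps[[1L]]$snps)
  for (k in seq_along(maps)) out[, (col_names[k]) := maps[[k]]$rate]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a recombination map file written by [write_recmap()]
#'
#' @param path TSV path.
#' @return data.table with name, chrom, bp and one column per map.
#' @export
read_recmap <- function(path) {
  out <- fread(path, sep = "\t")
  validate_snps(out)
  out
}
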