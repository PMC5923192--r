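#' Mendelian single-site phasing of a trio
#'
#' Phases one animal against its parents' genotypes using deterministic
#' single-site rules: a homozygous child is phased trivially; a heterozygous
#' child is phased when one parent's genotype forces the transmitted allele
#' (that parent homozygous, or the other parent homozygous which fixes its own
#' contribution); otherwise the site stays unknown. Sites violating Mendelian
#' inheritance (e.g. child 0 with a parent 2) are flagged and left unknown in
#' the child. Missing genotypes (-1) are allowed anywhere; an entirely
#' ungenotyped parent may be passed as `NULL`.
#'
#' @param child,father,mother integer genotype vectors (0/1/2, -1 missing) of
#'   equal length; `father`/`mother` may be `NULL`.
#' @return object of class `phased_pair`: list with `h1` (paternal haplotype),
#'   `h2` (maternal haplotype), both integer vectors with `NA` for unknown,
#'   `geno` (the child genotypes with flagged sites set missing) and `mendel`
#'   (integer indices of Mendelian-error sites).
#' @export
phase_trio <- function(child, father = NULL, mother = NULL) {
  n <- length(child)
  if (is.null(father)) father <- rep.int(-1L, n)
  if (is.null(mother)) mother <- rep.int(-1L, n)
  if (length(father) != n || length(mother) != n)
    stop("genotype vectors differ in length")
  c0 <- as.integer(child); f <- as.integer(father); m <- as.integer(mother)
  err <- (c0 == 0L & (f == 2L | m == 2L)) |
    (c0 == 2L & (f == 0L | m == 0L)) |
    (c0 == 1L & f == 2L & m == 2L) |
    (c0 == 1L & f == 0L & m == 0L)
  h1 <- rep.int(NA_integer_, n)
  h2 <- rep.int(NA_integer_, n)
  ok <- !err
  h1[ok & c0 == 0L] <- 0L; h2[ok & c0 == 0L] <- 0L
  h1[ok & c0 == 2L] <- 1L; h2[ok & c0 == 2L] <- 1L
  het <- ok & c0 == 1L
  pa <- rep.int(NA_integer_, n)
  pa[het & f == 0L] <- 0L
  pa[het & f == 2L] <- 1L
  und <- het & is.na(pa)
  pa[und & m == 0L] <- 1L       # maternal allele forced to 0
  pa[und & m == 2L] <- 0L       # maternal allele forced to 1
  h1[het] <- pa[het]
  h2[het] <- 1L - pa[het]
  geno <- c0
  geno[err] <- -1L
  structure(list(h1 = h1, h2 = h2, geno = geno, mendel = which(err)),
            class = "phased_pair")
}

#' Informative sites of a phased donor
#'
#' Exactly the sites at which the donor is heterozygous and both haplotypes
#' are phased, so the allele an offspring inherited identifies the donor
#' haplotype it came from.
#'
#' @param donor a [phase_trio()] result.
#' @return ordered integer vector of site indices.
#' @export
informative_sites <- function(donor) {
  stopifnot(inherits(donor, "phased_pair"))
  which(!is.na(donor$h1) & !is.na(donor$h2) & donor$h1 != donor$h2)
}
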