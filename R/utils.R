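# Shared internal helpers: interval bookkeeping on an ordered SNP table.
#
# Global convention (matches the on-disk map layout): SNP rows are in genome
# order (chromosome, then bp). Interval i is (bp[i-1], bp[i]] on the same
# chromosome and is stored on the row of its right SNP; the first SNP of each
# chromosome has no interval.

# logical vector: TRUE where the row opens a new chromosome (no interval)
chrom_first <- function(snps) {
  c(TRUE, snps$chrom[-1L] != snps$chrom[-nrow(snps)])
}

# bp width of each interval; 0 on chromosome-first rows
interval_width <- function(snps) {
  w <- c(0, diff(snps$bp))
  w[chrom_first(snps)] <- 0
  w
}

# validate an ordered SNP table (data.table with name, chrom, bp)
validate_snps <- function(snps) {
  stopifnot(all(c("name", "chrom", "bp") %in% names(snps)))
  if (anyDuplicated(snps$name))
    stop("duplicated SNP names: ", snps$name[duplicated(snps$name)][1L])
  ord <- order(snps$chrom, snps$bp)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNP table not in genome order (chromosome, then bp)")
  first <- chrom_first(snps)
  bad <- which(!first & c(0, diff(snps$bp)) <= 0)
  if (length(bad))
    stop("SNP positions not strictly increasing within chromosome at row ",
         bad[1L], " (", snps$name[bad[1L]], ")")
  invisible(snps)
}

same_snps <- function(a, b) {
  identical(a$name, b$name) && identical(a$chrom, b$chrom) &&
    identical(a$bp, b$bp)
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
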