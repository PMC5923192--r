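#' Genomic relationship matrix (centered cross-product)
#'
#' `K = C C' / (2 * sum p_j (1 - p_j))` with `C` the genotype matrix centered
#' by twice the allele frequency per SNP. Missing genotypes are mean-imputed
#' per SNP before centering; monomorphic SNPs carry no information and are
#' dropped. Under Hardy-Weinberg sampling the diagonal averages near 1.
#'
#' @param geno genotype matrix (animals x SNPs, 0/1/2, -1 or `NA` missing).
#' @param freqs optional allele frequencies per SNP; default estimated from
#'   the (imputed) column means.
#' @return symmetric n x n matrix with animal dimnames.
#' @export
compute_grm <- function(geno, freqs = NULL) {
  G <- geno
  storage.mode(G) <- "double"
  G[G < 0] <- NA
  if (nrow(G) < 2L) stop("compute_grm: need at least 2 animals")
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na)) G[na] <- mu[na[, 2L]]
  p <- if (is.null(freqs)) mu / 2 else freqs
  if (length(p) != ncol(G)) stop("freqs length does not match SNP count")
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("compute_grm: no polymorphic SNPs")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  C <- sweep(G, 2L, 2 * p)
  K <- tcrossprod(C) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

#' Pedigree-based additive relationship matrix
#'
#' Tabular (recursive) expected-relationship matrix: founders are unrelated
#' and non-inbred; `A[i,i] = 1 + A[s,d]/2`, `A[i,j] = (A[j,s] + A[j,d])/2`.
#' An alternative kinship for the mixed model when genotypes are sparse.
#'
#' @param ped data.frame/data.table with `id`, `sire`, `dam` (`NA`/`"0"` for
#'   unknown); any order, cycles rejected.
#' @return symmetric matrix with ids as dimnames.
#' @export
pedigree_amatrix <- function(ped) {
  ped <- as.data.table(ped)[, .(id, sire, dam)]
  ped[sire == "0", sire := NA_character_]
  ped[dam == "0", dam := NA_character_]
  .check_acyclic(ped)
  # order parents before offspring
  ord <- character(0)
  remaining <- copy(ped)
  while (nrow(remaining)) {
    ready <- remaining[(is.na(sire) | sire %in% ord | !sire %in% ped$id) &
                         (is.na(dam) | dam %in% ord | !dam %in% ped$id)]
    ord <- c(ord, ready$id)
    remaining <- remaining[!id %in% ready$id]
  }
  n <- length(ord)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  pos <- setNames(seq_len(n), ord)
  si <- pos[ped$sire[match(ord, ped$id)]]
  di <- pos[ped$dam[match(ord, ped$id)]]
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      as <- if (!is.na(s)) A[js, s] else rep.int(0, i - 1L)
      ad <- if (!is.na(d)) A[js, d] else rep.int(0, i - 1L)
      A[js, i] <- A[i, js] <- (as + ad) / 2
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  A[ped$id, ped$id]
}

# restricted log-likelihood pieces after eigen-rotation, profiled in the
# variance ratio lambda = sigma_a^2 / sigma_e^2
.reml_profile <- function(log10_lambda, yt, Xt, s, n, p, ldet_xtx) {
  lam <- 10^log10_lambda
  w <- lam * s + 1
  v <- 1 / w
  XtW <- Xt * v
  A <- crossprod(Xt, XtW)
  b <- solve(A, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  rss <- sum(r^2 * v)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
                  as.numeric(determinant(A, logarithm = TRUE)$modulus) -
                  ldet_xtx)
  list(ll = ll, s2 = s2, lambda = lam)
}

#' REML fit of the null variance-component model
#'
#' Fits `y = X b + a + e` with `a ~ N(0, sigma_a^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood. `K` is
#' eigendecomposed once; the restricted likelihood, profiled in
#' `sigma_e^2`, is maximized over the variance ratio
#' `lambda = sigma_a^2 / sigma_e^2` by bounded one-dimensional search on the
#' log scale in `[1e-5, 1e5]`.
#'
#' @param y phenotype vector.
#' @param K kinship/relationship matrix (symmetric PSD).
#' @param X fixed-effect design matrix; default intercept only.
#' @return object of class `reml_fit`: lambda, sigma_a2, sigma_e2,
#'   heritability, loglik, status (`"ok"`, `"boundary"` or
#'   `"indeterminate"` when the profile is flat, e.g. `K = I`), plus the
#'   cached eigenvectors `U` and eigenvalues `s` reused by [snp_scan()].
#' @export
fit_null_reml <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(K) == n, ncol(K) == n, n > p)
  eg <- eigen(K, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  ldet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  obj <- function(l) .reml_profile(l, yt, Xt, s, n, p, ldet_xtx)$ll
  opt <- optimize(obj, interval = c(-5, 5), maximum = TRUE, tol = 1e-7)
  if (!is.finite(opt$objective))
    stop("fit_null_reml: non-finite restricted likelihood at lambda = 10^",
         round(opt$maximum, 3))
  at_lo <- obj(-5); at_hi <- obj(5)
  status <- "ok"
  lambda <- 10^opt$maximum
  if (max(opt$objective - at_lo, opt$objective - at_hi,
          abs(at_hi - at_lo)) < 1e-6) {
    status <- "indeterminate"          # flat profile (e.g. K = I)
    lambda <- 0
  } else if (opt$maximum < -4.99 || abs(opt$maximum - 5) < 0.01) {
    status <- "boundary"
    if (opt$maximum < -4.99) lambda <- 0
  }
  prof <- .reml_profile(log10(max(lambda, 1e-300)), yt, Xt, s, n, p, ldet_xtx)
  if (lambda == 0) {
    # OLS limit
    b <- solve(crossprod(X), crossprod(X, y))
    s2 <- sum((y - X %*% b)^2) / (n - p)
    prof$s2 <- s2
  }
  sigma_e2 <- prof$s2
  sigma_a2 <- lambda * sigma_e2
  structure(list(lambda = lambda, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 heritability = sigma_a2 / (sigma_a2 + sigma_e2),
                 loglik = opt$objective, status = status,
                 U = U, s = s, X = X, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit: sigma_a2 =", signif(x$sigma_a2, 4),
      "sigma_e2 =", signif(x$sigma_e2, 4),
      "h2 =", signif(x$heritability, 3),
      paste0("(", x$status, ")"), "\n")
  invisible(x)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Two independent routes to the same quantity: `"eigen"` uses the rotated
#' representation that the fitting code is built on; `"dense"` evaluates the
#' textbook restricted likelihood with explicit `V = sigma_a^2 K +
#' sigma_e^2 I` inversion. Used to cross-check the fitter.
#'
#' @param sigma_a2,sigma_e2 variance components (`sigma_e2 > 0`).
#' @param y,K,X model pieces as in [fit_null_reml()].
#' @param method `"eigen"` or `"dense"`.
#' @return restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma_a2, sigma_e2, y, K, X = NULL,
                        method = c("eigen", "dense")) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(sigma_e2 > 0, sigma_a2 >= 0)
  ldet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  if (method == "dense") {
    V <- sigma_a2 * K + sigma_e2 * diag(n)
    Vi <- solve(V)
    XtVX <- crossprod(X, Vi %*% X)
    b <- solve(XtVX, crossprod(X, Vi %*% y))
    r <- y - X %*% b
    ypy <- as.numeric(crossprod(r, Vi %*% r))
    -0.5 * (as.numeric(determinant(V, logarithm = TRUE)$modulus) +
              as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
              ypy + (n - p) * log(2 * pi) - ldet_xtx)
  } else {
    eg <- eigen(K, symmetric = TRUE)
    s <- pmax(eg$values, 0)
    U <- eg$vectors
    yt <- crossprod(U, y); Xt <- crossprod(U, X)
    lam <- sigma_a2 / sigma_e2
    w <- lam * s + 1
    v <- 1 / w
    A <- crossprod(Xt, Xt * v)
    b <- solve(A, crossprod(Xt * v, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 * v)
    -0.5 * (n * log(sigma_e2) + sum(log(w)) +
              as.numeric(determinant(A, logarithm = TRUE)$modulus) -
              p * log(sigma_e2) + rss / sigma_e2 +
              (n - p) * log(2 * pi) - ldet_xtx)
  }
}

#' Mixed-model association scan
#'
#' Generalized least squares of the phenotype on `[1, g]` per SNP under the
#' covariance structure `sigma_a^2 K + sigma_e^2 I` fixed from the null REML
#' fit (one-step approximation; the correlation structure is held, the
#' residual scale is re-estimated per SNP). The SNP effect is tested by Wald
#' chi-square with 1 df. With `sigma_a^2 = 0` (or an indeterminate fit) the
#' scan reduces exactly to ordinary regression. Monomorphic SNPs are skipped
#' with `NA` results.
#'
#' @param y phenotype vector (same order as `geno` rows).
#' @param geno genotype matrix (animals x SNPs, -1/`NA` missing; missing
#'   calls are mean-imputed).
#' @param fit a [fit_null_reml()] result on the same animals.
#' @param snps optional SNP table (name, chrom, bp) for annotation.
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return data.table: snp, chrom, bp, beta, se, stat, p, sig.
#' @export
snp_scan <- function(y, geno, fit, snps = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "reml_fit"), length(y) == nrow(geno),
            fit$n == length(y))
  G <- geno
  storage.mode(G) <- "double"
  G[G < 0] <- NA
  mu <- colMeans(G, na.rm = TRUE)
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na)) G[na] <- mu[na[, 2L]]
  mono <- apply(G, 2L, function(g) max(g) - min(g)) == 0
  n <- length(y)
  w <- fit$lambda * fit$s + 1
  v <- 1 / w
  U <- fit$U
  yt <- as.numeric(crossprod(U, y))
  ot <- as.numeric(crossprod(U, rep(1, n)))
  Gt <- crossprod(U, G)
  S11 <- sum(v * ot^2)
  S1y <- sum(v * ot * yt)
  Syy <- sum(v * yt^2)
  S1g <- colSums(Gt * (v * ot))
  Sgy <- colSums(Gt * (v * yt))
  Sgg <- colSums(Gt^2 * v)
  D <- S11 * Sgg - S1g^2
  bad <- mono | D <= .Machine$double.eps * S11 * Sgg
  D[bad] <- NA_real_
  beta <- (S11 * Sgy - S1g * S1y) / D
  b0 <- (Sgg * S1y - S1g * Sgy) / D
  rss <- pmax(Syy - b0 * S1y - beta * Sgy, 0)
  s2 <- rss / (n - 2L)
  se <- sqrt(s2 * S11 / D)
  stat <- (beta / se)^2
  beta[bad] <- NA_real_; se[bad] <- NA_real_; stat[bad] <- NA_real_
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  n_test <- sum(!bad)
  out <- data.table(
    snp = colnames(geno) %||% paste0("snp", seq_len(ncol(geno))),
    beta = beta, se = se, stat = stat, p = p,
    sig = !is.na(p) & p < alpha / n_test
  )
  if (!is.null(snps)) {
    snps <- as.data.table(snps)
    out[, `:=`(chrom = snps$chrom[match(snp, snps$name)],
               bp = snps$bp[match(snp, snps$name)])]
    setcolorder(out, c("snp", "chrom", "bp"))
  }
  setattr(out, "bonferroni", alpha / n_test)
  out
}
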