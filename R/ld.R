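#' Keep common SNPs (MAF strictly above a threshold)
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param mafMin threshold; SNPs with MAF > mafMin are kept (strict, so a
#'   SNP at exactly the threshold is removed). Default 0.10.
#' @return filtered \linkS4class{GenotypeMatrix}, SNP order preserved.
#' @export
filterCommon <- function(genotypes, mafMin = 0.10) {
  maf <- .mafFromCalls(genotypeCalls(genotypes))
  keep <- !is.na(maf) & maf > mafMin
  if (!any(keep)) warning("no SNPs pass MAF > ", mafMin)
  subsetGenotypes(genotypes, snps = which(keep))
}

#' SNP density in bp per SNP
#'
#' @param nSnps number of SNPs observed.
#' @param totalBp total sequence length surveyed.
#' @return totalBp / nSnps (e.g. 24 means 1 SNP per 24 bp).
#' @export
snpDensity <- function(nSnps, totalBp) {
  if (totalBp <= 0) stop("totalBp must be positive")
  if (nSnps == 0) stop("no SNPs: density undefined")
  totalBp / nSnps
}

#' Composite genotypic LD r-squared between two SNPs
#'
#' r2 is the squared Pearson correlation of the minor-allele-count vectors
#' over individuals with both calls present (unphased composite LD; it is
#' symmetric in SNP order and invariant to which allele is counted at
#' either locus).
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param snp1,snp2 SNP ids or column indices.
#' @return data.frame(snp_id1, snp_id2, distance_bp, r2, n_used, reason);
#'   r2 is NA with a reason when either SNP is monomorphic on the
#'   complete-case subset.
#' @export
ldR2 <- function(genotypes, snp1, snp2) {
  sd_ <- snpInfo(genotypes)
  cl <- genotypeCalls(genotypes)
  ix <- function(s) if (is.character(s)) match(s, sd_$snp_id) else s
  i <- ix(snp1); j <- ix(snp2)
  if (is.na(i) || is.na(j)) stop("unknown SNP id")
  x <- cl[, i]; y <- cl[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dist <- if (!is.na(sd_$chrom[i]) && identical(sd_$chrom[i], sd_$chrom[j]))
    abs(sd_$pos[i] - sd_$pos[j]) else NA_integer_
  out <- data.frame(snp_id1 = sd_$snp_id[i], snp_id2 = sd_$snp_id[j],
                    distance_bp = dist, r2 = NA_real_,
                    n_used = sum(ok), reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
    out$reason <- "monomorphic_after_complete_case"
    return(out)
  }
  # duplicated or mirrored columns are exactly r2 = 1, free of rounding
  if (all(x == y) || all(x == 2 - y)) out$r2 <- 1
  else out$r2 <- stats::cor(x, y)^2
  out
}

#' All pairwise LD values for a set of SNPs
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param snps SNP ids/indices (default: all polymorphic SNPs).
#' @param gene restrict to SNPs of one gene (intragenic pairs), or NULL.
#' @return data.frame of \code{\link{ldR2}} rows for every unordered pair.
#' @export
ldPairs <- function(genotypes, snps = NULL, gene = NULL) {
  sd_ <- snpInfo(genotypes)
  if (!is.null(gene)) snps <- sd_$snp_id[!is.na(sd_$gene_id) &
                                           sd_$gene_id == gene]
  if (is.null(snps)) snps <- sd_$snp_id[!sd_$monomorphic]
  if (is.character(snps)) snps <- match(snps, sd_$snp_id)
  if (length(snps) < 2L) stop("need at least two SNPs")
  combs <- utils::combn(snps, 2)
  do.call(rbind, lapply(seq_len(ncol(combs)), function(k)
    ldR2(genotypes, combs[1, k], combs[2, k])))
}

# Hill-Weir expectation of r2 at scaled distance Cd with sample size n:
# a drift-recombination expectation plus a finite-sample correction that
# tends to 1/n at large distance.
.hillWeirEr2 <- function(Cd, n) {
  ((10 + Cd) / ((2 + Cd) * (11 + Cd))) *
    (1 + ((3 + Cd) * (12 + 12 * Cd + Cd^2)) / (n * (2 + Cd) * (11 + Cd)))
}

#' Fit the expected-r2 LD decay curve
#'
#' Fits the Hill-Weir expectation E(r2) = f(C * d, n) to observed pairwise
#' r2 values by nonlinear least squares over the single positive parameter
#' C (the per-bp population recombination parameter), with the sample size
#' n entering the finite-sample correction term. The fitted curve is
#' monotone non-increasing in distance and tends to 1/n.
#'
#' @param pairs data.frame with columns \code{distance_bp} and \code{r2}
#'   (rows with NA in either are dropped); needs >= 5 pairs spanning >= 2
#'   distinct distances.
#' @param n sample size (number of individuals).
#' @return an \linkS4class{LdDecayFit}.
#' @export
fitLdDecay <- function(pairs, n) {
  d <- pairs$distance_bp
  r2 <- pairs$r2
  ok <- !is.na(d) & !is.na(r2)
  d <- as.numeric(d[ok]); r2 <- r2[ok]
  if (length(d) < 5L) stop("need at least 5 usable pairs")
  if (length(unique(d)) < 2L) stop("need pairs at >= 2 distinct distances")
  rss <- function(logC) sum((r2 - .hillWeirEr2(exp(logC) * d, n))^2)
  lo <- log(1e-10); hi <- log(1e3)
  opt <- stats::optimize(rss, c(lo, hi), tol = 1e-12)
  # polish around the optimum for tight recovery on noiseless data
  opt2 <- stats::optimize(rss, c(max(lo, opt$minimum - 0.05),
                                 min(hi, opt$minimum + 0.05)), tol = 1e-14)
  if (opt2$objective < opt$objective) opt <- opt2
  ldDecayFit(C = exp(opt$minimum), n = n, rss = opt$objective,
             nPairs = length(d), boundary = opt$minimum <= lo + 1e-6)
}

#' Distance at which the fitted decay curve first drops below a threshold
#'
#' @param fit an \linkS4class{LdDecayFit}.
#' @param threshold r2 level (default 0.1, the conventional reporting
#'   level for rapid decay).
#' @return distance in bp, or \code{Inf} when the curve never drops below
#'   the threshold (boundary fits, or threshold at or below the 1/n
#'   asymptote).
#' @export
crossingBp <- function(fit, threshold = 0.1) {
  stopifnot(is(fit, "LdDecayFit"))
  f <- function(d) .hillWeirEr2(fit@C * d, fit@n) - threshold
  if (fit@boundary || f(0) <= 0) {
    if (f(0) <= 0) return(0)
    return(Inf)
  }
  upper <- 1e12
  if (f(upper) >= 0) return(Inf)
  stats::uniroot(f, c(1e-9, upper), tol = 1e-9)$root
}
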