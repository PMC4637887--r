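# complete-case restriction shared by the association tests
.completeCases <- function(y, g, Q) {
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(Q)) ok <- ok & stats::complete.cases(Q)
  list(y = y[ok], g = g[ok],
       Q = if (is.null(Q)) NULL else Q[ok, , drop = FALSE])
}

# drop genotype classes with fewer than minClassN individuals
.dropSmallClasses <- function(y, g, Q, minClassN) {
  tab <- table(g)
  keepClasses <- as.numeric(names(tab)[tab >= minClassN])
  ok <- g %in% keepClasses
  list(y = y[ok], g = g[ok],
       Q = if (is.null(Q)) NULL else Q[ok, , drop = FALSE],
       classes = keepClasses)
}

# adjusted value of each observation at the covariate mean
.adjustToQbar <- function(fit, Q, y) {
  if (is.null(Q)) return(y - fit$resid + fit$resid)  # = y
  betaQ <- fit$coef[1 + seq_len(ncol(Q))]
  betaQ[is.na(betaQ)] <- 0
  centered <- sweep(Q, 2, colMeans(Q))
  y - as.numeric(centered %*% betaQ)
}

#' Genotypic (2-df) effect test for one SNP and one trait
#'
#' Compares \code{y ~ Q + genotype(factor)} against \code{y ~ Q} by an
#' extra-sum-of-squares F test on complete cases. The variance explained
#' is the drop in residual SS relative to the total SS of the trait, and
#' class means are adjusted to the covariate mean. Genotype classes with
#' fewer than \code{minClassN} individuals are excluded; a SNP with fewer
#' than two remaining classes is skipped with a reason code.
#'
#' @param y numeric trait vector.
#' @param g genotype codes 0/1/2 (NA allowed).
#' @param Q optional covariate matrix (rows matching y).
#' @param minClassN minimum individuals per genotype class (default 3).
#' @return list(status, reason, m_p, r2_explained, genotype_means, n_used).
#' @export
genotypicTest <- function(y, g, Q = NULL, minClassN = 3L) {
  cc <- .completeCases(y, g, Q)
  dd <- .dropSmallClasses(cc$y, cc$g, cc$Q, minClassN)
  skip <- function(reason)
    list(status = "skipped", reason = reason, m_p = NA_real_,
         r2_explained = NA_real_, genotype_means = NULL,
         n_used = length(dd$y))
  if (length(dd$classes) < 2L) return(skip("fewer_than_2_classes"))
  y2 <- dd$y; g2 <- dd$g; Q2 <- dd$Q
  Xred <- cbind(`(Intercept)` = rep(1, length(y2)), Q2)
  fac <- factor(g2)
  dummies <- stats::model.matrix(~ fac)[, -1, drop = FALSE]
  Xfull <- cbind(Xred, dummies)
  full <- .ols(Xfull, y2)
  ft <- .fTest(full, Xred, y2)
  ssTot <- sum((y2 - mean(y2))^2)
  adj <- .adjustToQbar(full, Q2, y2)
  means <- tapply(adj, g2, mean)
  list(status = "ok", reason = NA_character_,
       m_p = ft$p,
       r2_explained = if (ssTot > 0) (ft$sseRed - full$sse) / ssTot
                      else NA_real_,
       genotype_means = means, n_used = length(y2))
}

#' Additive and dominance effect tests for one SNP and one trait
#'
#' Fits \code{y ~ Q + x + z} with the additive code x in \{-1, 0, +1\}
#' and the dominance code z = +0.5 for heterozygotes, -0.5 otherwise, so
#' the additive coefficient is half the homozygote difference and the
#' dominance coefficient is the heterozygote deviation from the homozygote
#' midpoint. Each coefficient gets a 1-df t test. With only two genotype
#' classes present (after dropping classes below \code{minClassN}) the
#' dominance code is confounded with the additive code, so only the
#' additive slope is estimated and d is reason-coded.
#'
#' @inheritParams genotypicTest
#' @return list(status, reason, a_hat, a_p, d_hat, d_p, n_used).
#' @export
additiveDominanceTest <- function(y, g, Q = NULL, minClassN = 3L) {
  cc <- .completeCases(y, g, Q)
  dd <- .dropSmallClasses(cc$y, cc$g, cc$Q, minClassN)
  out <- list(status = "ok", reason = NA_character_, a_hat = NA_real_,
              a_p = NA_real_, d_hat = NA_real_, d_p = NA_real_,
              n_used = length(dd$y))
  if (length(dd$classes) < 2L) {
    out$status <- "skipped"; out$reason <- "fewer_than_2_classes"
    return(out)
  }
  y2 <- dd$y; Q2 <- dd$Q
  codes <- .geneticCodes(dd$g)
  threeClass <- length(dd$classes) == 3L
  X <- cbind(`(Intercept)` = rep(1, length(y2)), Q2, x = codes$x)
  jx <- ncol(X)
  if (threeClass) X <- cbind(X, z = codes$z)
  fit <- .ols(X, y2)
  se <- .olsSe(fit)
  out$a_hat <- unname(fit$coef[jx])
  out$a_p <- .tTest(fit, se, jx)
  if (threeClass) {
    jz <- ncol(X)
    out$d_hat <- unname(fit$coef[jz])
    out$d_p <- .tTest(fit, se, jz)
  } else out$reason <- "two_class_no_dominance"
  out
}

#' Significance transform log10(1/p)
#'
#' @param p p-value(s) in (0, 1].
#' @return log10(1/p); 0 for p = 1, 3 for p = 0.001.
#' @export
significanceTransform <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  log10(1 / p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (monotone, permutation-invariant), delegated to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p vector of p-values in (0, 1]; NAs are passed through.
#' @return q-values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  pp <- p[!is.na(p)]
  if (any(pp <= 0) || any(pp > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Unadjusted genotype-class deviations from the grand mean
#'
#' For Fig-3-style summaries: raw class means minus the overall trait
#' mean, with class counts. Over complete cases the count-weighted
#' deviations sum to zero.
#'
#' @param y trait vector.
#' @param g genotype codes 0/1/2.
#' @param alleles optional c(major, minor) single-base labels; when given,
#'   classes are labelled e.g. "AA", "AG", "GG" instead of 0/1/2.
#' @return data.frame(genotype, n, mean, deviation).
#' @export
genotypeDeviations <- function(y, g, alleles = NULL) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  grand <- mean(y)
  classes <- sort(unique(g))
  lab <- as.character(classes)
  if (!is.null(alleles)) {
    stopifnot(length(alleles) == 2L)
    lab <- c(paste0(alleles[1], alleles[1]),
             paste0(alleles[1], alleles[2]),
             paste0(alleles[2], alleles[2]))[classes + 1]
  }
  means <- vapply(classes, function(k) mean(y[g == k]), numeric(1))
  data.frame(genotype = lab, n = vapply(classes, function(k) sum(g == k),
                                        integer(1)),
             mean = means, deviation = means - grand,
             stringsAsFactors = FALSE)
}

#' Single-locus association scan over SNPs and traits
#'
#' Runs \code{\link{genotypicTest}} and
#' \code{\link{additiveDominanceTest}} for every SNP x trait combination,
#' applies Benjamini-Hochberg FDR within each (trait, effect-type) family,
#' and flags associations significant at \code{p <= alpha} and
#' \code{q <= fdrMax}. Monomorphic SNPs and SNPs failing the class-count
#' rule are reported with a skip reason, never silently dropped.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param phenotypes data.frame of traits, individual ids as rownames.
#' @param covariates optional Q matrix with individual rownames.
#' @param traits trait names (default: all phenotype columns).
#' @param alpha per-test significance cutoff (default 0.01).
#' @param fdrMax FDR cutoff (default 0.1).
#' @param minClassN minimum genotype-class size (default 3).
#' @return data.frame, one row per SNP x trait, with test statistics,
#'   log10(1/p) significances, q-values and significance flags.
#' @export
scanSingleLocus <- function(genotypes, phenotypes, covariates = NULL,
                            traits = NULL, alpha = 0.01, fdrMax = 0.1,
                            minClassN = 3L) {
  co <- alignCohort(genotypes, phenotypes, covariates)
  cl <- genotypeCalls(co$genotypes)
  sd_ <- snpInfo(co$genotypes)
  if (is.null(traits)) traits <- colnames(co$phenotypes)
  rows <- vector("list", length(traits) * ncol(cl))
  k <- 0L
  for (tr in traits) {
    y <- co$phenotypes[[tr]]
    for (j in seq_len(ncol(cl))) {
      k <- k + 1L
      g <- cl[, j]
      if (sd_$monomorphic[j]) {
        rows[[k]] <- data.frame(
          snp_id = sd_$snp_id[j], gene_id = sd_$gene_id[j], trait = tr,
          n_used = sum(!is.na(g) & !is.na(y)), m_p = NA_real_,
          r2_explained = NA_real_, a_hat = NA_real_, a_p = NA_real_,
          d_hat = NA_real_, d_p = NA_real_, status = "skipped",
          reason = "monomorphic", stringsAsFactors = FALSE)
        next
      }
      gt <- genotypicTest(y, g, co$covariates, minClassN)
      ad <- additiveDominanceTest(y, g, co$covariates, minClassN)
      rows[[k]] <- data.frame(
        snp_id = sd_$snp_id[j], gene_id = sd_$gene_id[j], trait = tr,
        n_used = gt$n_used, m_p = gt$m_p, r2_explained = gt$r2_explained,
        a_hat = ad$a_hat, a_p = ad$a_p, d_hat = ad$d_hat, d_p = ad$d_p,
        status = if (gt$status == "ok" || ad$status == "ok") "ok"
                 else "skipped",
        reason = if (!is.na(ad$reason)) ad$reason else gt$reason,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  sig <- function(p) ifelse(is.na(p) | p <= 0, NA_real_, log10(1 / p))
  res$m_sig <- sig(res$m_p)
  res$a_sig <- sig(res$a_p)
  res$d_sig <- sig(res$d_p)
  for (fam in c("m", "a", "d")) {
    pc <- paste0(fam, "_p"); qc <- paste0(fam, "_q")
    res[[qc]] <- NA_real_
    for (tr in traits) {
      sel <- res$trait == tr & !is.na(res[[pc]])
      if (any(sel)) res[[qc]][sel] <- bhAdjust(res[[pc]][sel])
    }
    res[[paste0("significant_", fam)]] <-
      !is.na(res[[pc]]) & res[[pc]] <= alpha &
      !is.na(res[[qc]]) & res[[qc]] <= fdrMax
  }
  ord <- c("snp_id", "gene_id", "trait", "n_used",
           "m_p", "m_sig", "m_q", "r2_explained",
           "a_hat", "a_p", "a_sig", "a_q",
           "d_hat", "d_p", "d_sig", "d_q",
           "significant_m", "significant_a", "significant_d",
           "status", "reason")
  res[, ord]
}
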