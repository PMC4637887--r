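.EPI_TYPES <- c("AxA", "AxD", "DxA", "DxD")

#' Two-locus genetic design columns
#'
#' Builds the eight coded columns of the two-locus model: single-locus
#' additive (x, in \{-1,0,+1\}) and dominance (z, \{-0.5,+0.5,-0.5\})
#' codes at each locus plus their four products x1x2 (AxA), x1z2 (AxD),
#' z1x2 (DxA) and z1z2 (DxD). With exactly balanced 3x3 cell counts the
#' eight columns are mutually orthogonal; least squares on them with the
#' observed (generally unequal) genotype frequencies realizes the
#' frequency-weighted orthogonal-contrast partition of two-locus genotypic
#' values.
#'
#' @param g1,g2 genotype code vectors (0/1/2; complete cases expected).
#' @return data.frame(x1, z1, x2, z2, x1x2, x1z2, z1x2, z1z2) with the
#'   3x3 cell-count table in \code{attr(, "cells")}.
#' @export
twoLocusDesign <- function(g1, g2) {
  c1 <- .geneticCodes(g1)
  c2 <- .geneticCodes(g2)
  d <- data.frame(x1 = c1$x, z1 = c1$z, x2 = c2$x, z2 = c2$z,
                  x1x2 = c1$x * c2$x, x1z2 = c1$x * c2$z,
                  z1x2 = c1$z * c2$x, z1z2 = c1$z * c2$z)
  attr(d, "cells") <- table(factor(g1, 0:2), factor(g2, 0:2))
  d
}

# default occupancy rule for a pair test
.occupancyOk <- function(g1, g2, minMarginal, minCells) {
  t1 <- table(factor(g1, 0:2)); t2 <- table(factor(g2, 0:2))
  cells <- table(factor(g1, 0:2), factor(g2, 0:2))
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    return("monomorphic_locus")
  if (any(t1 < minMarginal) || any(t2 < minMarginal))
    return("marginal_class_below_minimum")
  if (sum(cells > 0) < minCells)
    return("too_few_occupied_cells")
  NA_character_
}

#' Pairwise SNP x SNP epistasis test
#'
#' Fits \code{y ~ Q + x1 + z1 + x2 + z2 + x1x2 + x1z2 + z1x2 + z1z2} by
#' least squares on complete cases and tests each of the four epistatic
#' coefficients with a 1-df full-vs-dropped-term F test, plus a joint
#' 4-df interaction test. Coefficients aliased by empty cells are
#' reported as non-estimable (NA), never as zero. Adjusted 3x3 cell means
#' are evaluated at the covariate mean; empty cells are NA.
#'
#' @param y trait vector.
#' @param g1,g2 genotype code vectors.
#' @param Q optional covariate matrix.
#' @param minMarginal minimum individuals in each marginal genotype class
#'   at each locus (default 3).
#' @param minCells minimum number of non-empty cells in the 3x3 table
#'   (default 5).
#' @return list(status, reason, n_used, cells, cell_means, effects
#'   (data.frame type/estimate/F/p), pair_p).
#' @export
epistasisTest <- function(y, g1, g2, Q = NULL, minMarginal = 3L,
                          minCells = 5L) {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  if (!is.null(Q)) ok <- ok & stats::complete.cases(Q)
  y <- y[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  if (!is.null(Q)) Q <- Q[ok, , drop = FALSE]
  out <- list(status = "ok", reason = NA_character_, n_used = length(y),
              cells = table(factor(g1, 0:2), factor(g2, 0:2)),
              cell_means = matrix(NA_real_, 3, 3,
                                  dimnames = list(0:2, 0:2)),
              effects = data.frame(type = .EPI_TYPES,
                                   estimate = NA_real_, F = NA_real_,
                                   p = NA_real_,
                                   stringsAsFactors = FALSE),
              pair_p = NA_real_)
  reason <- .occupancyOk(g1, g2, minMarginal, minCells)
  if (!is.na(reason)) {
    out$status <- "skipped"; out$reason <- reason
    return(out)
  }
  D <- twoLocusDesign(g1, g2)
  base <- cbind(`(Intercept)` = rep(1, length(y)), Q)
  Xfull <- cbind(base, as.matrix(D[, c("x1", "z1", "x2", "z2")]),
                 as.matrix(D[, c("x1x2", "x1z2", "z1x2", "z1z2")]))
  full <- .ols(Xfull, y)
  # empty cells alias design columns; tests are run within the estimable
  # design (aliased effects stay NA, they are never forced to zero)
  aliased <- is.na(full$coef)
  Xeff <- Xfull[, !aliased, drop = FALSE]
  eff <- if (any(aliased)) .ols(Xeff, y) else full
  intNames <- stats::setNames(c("x1x2", "x1z2", "z1x2", "z1z2"), .EPI_TYPES)
  for (ty in .EPI_TYPES) {
    nm <- intNames[[ty]]
    est <- unname(full$coef[nm])
    row <- which(out$effects$type == ty)
    out$effects$estimate[row] <- est
    if (!is.na(est)) {
      ft <- .fTest(eff, Xeff[, colnames(Xeff) != nm, drop = FALSE], y)
      out$effects$F[row] <- ft$F
      out$effects$p[row] <- ft$p
    }
  }
  keepInt <- intNames[!intNames %in% colnames(Xfull)[aliased]]
  Xmain <- Xeff[, !colnames(Xeff) %in% keepInt, drop = FALSE]
  out$pair_p <- .fTest(eff, Xmain, y)$p
  adj <- .adjustToQbar(full, Q, y)
  for (a in 0:2) for (b in 0:2) {
    sel <- g1 == a & g2 == b
    if (any(sel)) out$cell_means[a + 1, b + 1] <- mean(adj[sel])
  }
  if (anyNA(out$effects$estimate)) {
    out$reason <- "non_estimable_effects"
  }
  out
}

# genotype class label from code and c(major, minor) alleles
.genoLabel <- function(code, alleles) {
  c(paste0(alleles[1], alleles[1]),
    paste0(alleles[1], alleles[2]),
    paste0(alleles[2], alleles[2]))[code + 1]
}

#' Allele/genotype combination effects and frequencies for a SNP pair
#'
#' Summaries in the style of an epistasis report table. For AxA, each
#' individual contributes its four ordered allele pairings (one allele
#' from each locus), each with weight 1/4; a combination's effect is the
#' weighted mean phenotype of its contributions minus the grand mean and
#' its frequency is its share of the total weight (so frequencies sum to
#' 1 and the frequency-weighted effects sum to 0). AxD crosses an allele
#' at locus 1 (weight 1/2 per copy) with the full genotype at locus 2;
#' DxA is the mirror (genotype at locus 1 by allele at locus 2); DxD uses
#' plain genotype-genotype cell means and cell frequencies. Rows are
#' sorted by effect, descending; empty combinations are omitted.
#'
#' @param y trait vector.
#' @param g1,g2 genotype codes.
#' @param effectType one of "AxA", "AxD", "DxA", "DxD".
#' @param alleles1,alleles2 c(major, minor) labels per locus (the major
#'   allele is the one the 0 genotype is homozygous for).
#' @return data.frame(combo, effect, frequency).
#' @export
combinationEffects <- function(y, g1, g2, effectType,
                               alleles1 = c("A", "a"),
                               alleles2 = c("B", "b")) {
  effectType <- match.arg(effectType, .EPI_TYPES)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- y[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(y)
  grand <- mean(y)
  # per-individual allele-copy counts: column 1 = major, column 2 = minor
  copies <- function(g) cbind(2 - g, g)
  a1 <- copies(g1); a2 <- copies(g2)
  rows <- list()
  addRow <- function(label, w) {
    tw <- sum(w)
    if (tw == 0) return()
    rows[[base::length(rows) + 1L]] <<- data.frame(
      combo = label, effect = sum(w * y) / tw - grand,
      frequency = tw / n, stringsAsFactors = FALSE)
  }
  if (effectType == "AxA") {
    for (u in 1:2) for (v in 1:2)
      addRow(paste0(alleles1[u], "-", alleles2[v]),
             (a1[, u] / 2) * (a2[, v] / 2))
  } else if (effectType == "AxD") {
    for (u in 1:2) for (G in 0:2)
      addRow(paste0(alleles1[u], "-", .genoLabel(G, alleles2)),
             (a1[, u] / 2) * (g2 == G))
  } else if (effectType == "DxA") {
    for (G in 0:2) for (v in 1:2)
      addRow(paste0(.genoLabel(G, alleles1), "-", alleles2[v]),
             (g1 == G) * (a2[, v] / 2))
  } else {
    for (G in 0:2) for (H in 0:2)
      addRow(paste0(.genoLabel(G, alleles1), "-", .genoLabel(H, alleles2)),
             as.numeric(g1 == G & g2 == H))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$effect), ]
  rownames(out) <- NULL
  out
}

#' Raw two-locus genotype-combination deviations from the grand mean
#'
#' Unadjusted 3x3 cell means minus the overall trait mean; empty cells
#' are NA.
#'
#' @param y trait vector.
#' @param g1,g2 genotype codes.
#' @return 3x3 matrix of deviations (rows = locus-1 codes 0/1/2).
#' @export
combinationDeviations <- function(y, g1, g2) {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- y[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  grand <- mean(y)
  m <- matrix(NA_real_, 3, 3, dimnames = list(0:2, 0:2))
  for (a in 0:2) for (b in 0:2) {
    sel <- g1 == a & g2 == b
    if (any(sel)) m[a + 1, b + 1] <- mean(y[sel]) - grand
  }
  m
}

#' All hub-SNP x target-SNP pairs
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param hubGene gene id of the hub; its SNPs are paired with every SNP
#'   of every other gene.
#' @return 2-column character matrix of SNP id pairs.
#' @export
hubTargetPairs <- function(genotypes, hubGene) {
  sd_ <- snpInfo(genotypes)
  hubSnps <- sd_$snp_id[!is.na(sd_$gene_id) & sd_$gene_id == hubGene]
  targetSnps <- sd_$snp_id[is.na(sd_$gene_id) | sd_$gene_id != hubGene]
  if (!length(hubSnps)) stop("no SNPs annotated to hub gene ", hubGene)
  cbind(snp_id1 = rep(hubSnps, each = length(targetSnps)),
        snp_id2 = rep(targetSnps, times = length(hubSnps)))
}

#' Epistasis scan over SNP pairs and traits
#'
#' Runs \code{\link{epistasisTest}} for every requested pair and trait,
#' with Benjamini-Hochberg FDR within each (trait, effect-type) family
#' and significance flags at \code{p <= alpha, q <= fdrMax}. Pairs that
#' fail the occupancy rule are reported with their skip reason.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param phenotypes trait data.frame (ids as rownames).
#' @param pairs 2-column matrix/data.frame of SNP ids (e.g. from
#'   \code{\link{hubTargetPairs}}).
#' @param covariates optional Q matrix.
#' @param traits trait names (default all).
#' @param alpha,fdrMax significance cutoffs (defaults 0.01, 0.1).
#' @param minMarginal,minCells occupancy rule (defaults 3, 5).
#' @return data.frame, one row per pair x trait x effect type, with
#'   estimate, p, q, the joint 4-df pair p, occupancy and skip reasons.
#' @export
scanEpistasis <- function(genotypes, phenotypes, pairs, covariates = NULL,
                          traits = NULL, alpha = 0.01, fdrMax = 0.1,
                          minMarginal = 3L, minCells = 5L) {
  co <- alignCohort(genotypes, phenotypes, covariates)
  cl <- genotypeCalls(co$genotypes)
  sd_ <- snpInfo(co$genotypes)
  geneOf <- stats::setNames(sd_$gene_id, sd_$snp_id)
  if (is.null(traits)) traits <- colnames(co$phenotypes)
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs) * length(traits))
  k <- 0L
  for (tr in traits) {
    y <- co$phenotypes[[tr]]
    for (i in seq_len(nrow(pairs))) {
      s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
      et <- epistasisTest(y, cl[, s1], cl[, s2], co$covariates,
                          minMarginal, minCells)
      k <- k + 1L
      rows[[k]] <- data.frame(
        snp_id1 = s1, gene1 = unname(geneOf[s1]),
        snp_id2 = s2, gene2 = unname(geneOf[s2]), trait = tr,
        effect_type = et$effects$type, estimate = et$effects$estimate,
        p = et$effects$p, pair_p = et$pair_p, n_used = et$n_used,
        cells_occupied = sum(et$cells > 0), status = et$status,
        reason = et$reason, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (tr in traits) for (ty in .EPI_TYPES) {
    sel <- res$trait == tr & res$effect_type == ty & !is.na(res$p)
    if (any(sel)) res$q[sel] <- bhAdjust(res$p[sel])
  }
  res$significant <- !is.na(res$p) & res$p <= alpha &
    !is.na(res$q) & res$q <= fdrMax
  res
}
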