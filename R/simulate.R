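#' Simulate biallelic genotypes under HWE with optional LD blocks
#'
#' Each SNP's two haplotypes are drawn independently as Bernoulli(MAF)
#' alleles (Hardy-Weinberg equilibrium at the requested frequency). Within
#' an LD block, every non-anchor SNP copies the block anchor's haplotype
#' state with probability \code{rho} per haplotype (otherwise it keeps an
#' independent draw), which gives tunable pairwise r-squared with the exact
#' r2 = 1 limit at rho = 1 for equal MAFs. Output is deterministic for a
#' given spec (the seed lives in the spec).
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A \linkS4class{GenotypeMatrix} with codes counting the minor
#'   allele as realized in the simulated cohort.
#' @export
simulateGenotypes <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nIndividuals
  m <- spec@nSnps
  maf <- if (length(spec@mafRange))
    stats::runif(m, spec@mafRange[1], spec@mafRange[2]) else spec@maf

  h1 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
  h2 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
  for (b in spec@ldBlocks) {
    anchor <- b$snps[1]
    for (s in setdiff(b$snps, anchor)) {
      copy1 <- stats::runif(n) < b$rho
      copy2 <- stats::runif(n) < b$rho
      h1[copy1, s] <- h1[copy1, anchor]
      h2[copy2, s] <- h2[copy2, anchor]
    }
  }
  calls <- h1 + h2
  freq <- colMeans(calls) / 2
  flip <- freq > 0.5
  calls[, flip] <- 2 - calls[, flip]

  inds <- sprintf("ind%03d", seq_len(n))
  ids <- paste0(spec@geneAssignment, "-SNP",
                stats::ave(seq_len(m), spec@geneAssignment, FUN = seq_along))
  rownames(calls) <- inds
  colnames(calls) <- ids
  snpData <- data.frame(
    snp_id = ids, chrom = spec@chrom, pos = spec@positions,
    ref = "A", alt = "G", gene_id = spec@geneAssignment,
    maf = .mafFromCalls(calls),
    counted = ifelse(flip, "ref", "alt"),
    stringsAsFactors = FALSE)
  snpData$monomorphic <- snpData$maf == 0
  genotypeMatrix(calls, snpData)
}

#' Simulate a quantitative trait from a genetic effect model
#'
#' Generates \code{y = mu + sum a_j x_j + sum d_j z_j + epistatic products
#' + Q beta + N(0, sigma^2)} with the additive code \code{x} in
#' \{-1, 0, +1\} for 0/1/2 minor-allele copies and the dominance code
#' \code{z} equal to +0.5 for heterozygotes and -0.5 otherwise. Epistatic
#' terms are products of the corresponding single-locus codes (AxA =
#' x1*x2, AxD = x1*z2, DxA = z1*x2, DxD = z1*z2).
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param model \linkS4class{EffectModel}.
#' @param covariates optional Q matrix (individuals x components) matching
#'   \code{model@structureEffects}.
#' @param seed RNG seed for the residual draw.
#' @param traitName column name of the simulated trait.
#' @return data.frame with one trait column, individual ids as rownames.
#' @export
simulatePhenotype <- function(genotypes, model, covariates = NULL,
                              seed = 1L, traitName = "trait") {
  validObject(model)
  cl <- genotypeCalls(genotypes)
  known <- colnames(cl)
  used <- unique(c(names(model@additive), names(model@dominance),
                   model@epistasis$snp1, model@epistasis$snp2))
  if (length(bad <- setdiff(used, known)))
    stop("effect model references unknown SNP(s): ",
         paste(bad, collapse = ", "))
  n <- nrow(cl)
  y <- rep(model@mu, n)
  for (s in names(model@additive))
    y <- y + model@additive[[s]] * (cl[, s] - 1)
  for (s in names(model@dominance))
    y <- y + model@dominance[[s]] * ifelse(cl[, s] == 1, 0.5, -0.5)
  if (nrow(model@epistasis)) {
    for (i in seq_len(nrow(model@epistasis))) {
      e <- model@epistasis[i, ]
      c1 <- .geneticCodes(cl[, e$snp1])
      c2 <- .geneticCodes(cl[, e$snp2])
      term <- switch(e$type,
                     AxA = c1$x * c2$x, AxD = c1$x * c2$z,
                     DxA = c1$z * c2$x, DxD = c1$z * c2$z)
      y <- y + e$coef * term
    }
  }
  if (length(model@structureEffects)) {
    Q <- .asCovariateMatrix(covariates, rownames(cl))
    if (is.null(Q)) stop("model has structure effects but no covariates given")
    y <- y + as.numeric(Q %*% model@structureEffects)
  }
  set.seed(seed)
  y <- y + stats::rnorm(n, 0, model@sigma)
  out <- data.frame(y, row.names = rownames(cl))
  names(out) <- traitName
  out
}

#' Simulate tissue expression profiles with planted hub correlations
#'
#' The hub profile is drawn standard normal over conditions, then shifted
#' positive. Each target listed in \code{targetCorrelations} is built as
#' \code{r * standardized(hub) + sqrt(1 - r^2) * noise} and shifted
#' positive by a constant, which preserves the Pearson correlation; the
#' realized r converges to the requested one as the number of conditions
#' grows and equals it exactly at |r| = 1. Genes not listed get
#' independent profiles.
#'
#' @param geneIds genes to simulate (the hub is added if absent).
#' @param hubGene hub gene id.
#' @param targetCorrelations named numeric, gene -> target Pearson r
#'   (|r| <= 1).
#' @param nConditions number of conditions/tissues (>= 3; default 4).
#' @param seed RNG seed.
#' @return numeric matrix genes x conditions, strictly positive. With 4
#'   conditions the columns are named after the study design's tissues.
#' @export
simulateExpression <- function(geneIds, hubGene,
                               targetCorrelations = numeric(0),
                               nConditions = 4L, seed = 1L) {
  if (nConditions < 3L) stop("need at least 3 conditions")
  if (any(abs(targetCorrelations) > 1)) stop("|r| must be <= 1")
  geneIds <- union(hubGene, geneIds)
  set.seed(seed)
  hub <- stats::rnorm(nConditions)
  hubStd <- as.numeric(scale(hub))
  shiftPos <- function(v) v - min(v) + 0.5
  m <- matrix(NA_real_, length(geneIds), nConditions,
              dimnames = list(geneIds,
                              if (nConditions == 4L)
                                c("leaf", "cambium", "developing_xylem",
                                  "mature_xylem")
                              else paste0("cond", seq_len(nConditions))))
  m[hubGene, ] <- shiftPos(hub)
  for (g in setdiff(geneIds, hubGene)) {
    if (g %in% names(targetCorrelations)) {
      r <- targetCorrelations[[g]]
      raw <- r * hubStd +
        if (abs(r) < 1) sqrt(1 - r^2) * stats::rnorm(nConditions) else 0
    } else raw <- stats::rnorm(nConditions)
    m[g, ] <- shiftPos(raw)
  }
  m
}

# greedy motif-free background fill: resample any base completing an
# avoided word (forward or reverse complement), honoring fixed planted bases
.fillBackground <- function(chars, fixed, avoid, gcProb) {
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - gcProb) / 2, gcProb / 2, gcProb / 2, (1 - gcProb) / 2)
  lens <- nchar(avoid)
  L <- length(chars)
  for (i in seq_len(L)) {
    if (fixed[i]) next
    cand <- sample(bases, 4L, prob = pr)   # preference order
    placed <- FALSE
    for (b in cand) {
      chars[i] <- b
      ok <- TRUE
      for (k in seq_along(avoid)) {
        w <- lens[k]
        if (i >= w &&
            !any(is.na(chars[(i - w + 1):i])) &&
            paste(chars[(i - w + 1):i], collapse = "") == avoid[k]) {
          ok <- FALSE
          break
        }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) chars[i] <- cand[1]  # resolved by the caller's verify loop
  }
  chars
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate promoter sequences with motifs planted at exact offsets
#'
#' Backgrounds are i.i.d. at the requested GC content, constrained (by
#' resampling collision windows) to contain no occurrence of the avoided
#' motifs on either strand, then the planned motifs are written at their
#' exact upstream offsets. Offsets follow the package convention: position
#' 1 is the base immediately 5' of the TSS, and a motif's offset is the
#' upstream position of its base closest to the TSS.
#'
#' @param motifPlan named list, gene -> data.frame(motif, offset); use an
#'   empty data.frame (or omit the gene from the plan and list it in
#'   \code{geneIds}) for motif-free promoters.
#' @param geneIds all genes to emit (default: names of the plan).
#' @param length promoter length in bp (default 2000).
#' @param gc background GC content in (0, 1).
#' @param avoidMotifs motifs guaranteed absent from backgrounds (both
#'   strands); defaults to the planted motifs plus the canonical WUS-box
#'   motifs TCACGTGA and TAAT so unplanted promoters scan clean.
#' @param seed RNG seed.
#' @return named \code{DNAStringSet} of promoters.
#' @export
plantPromoters <- function(motifPlan, geneIds = names(motifPlan),
                           length = 2000L, gc = 0.4,
                           avoidMotifs = NULL, seed = 1L) {
  set.seed(seed)
  planted <- unique(unlist(lapply(motifPlan, function(p)
    if (nrow(p)) as.character(p$motif) else character(0))))
  if (is.null(avoidMotifs))
    avoidMotifs <- unique(c(planted, "TCACGTGA", "TAAT"))
  avoidBoth <- unique(c(avoidMotifs, vapply(avoidMotifs, .revcomp,
                                            character(1))))
  out <- character(0)
  for (g in geneIds) {
    plan <- motifPlan[[g]]
    if (is.null(plan))
      plan <- data.frame(motif = character(0), offset = integer(0))
    spans <- NULL
    if (nrow(plan)) {
      k <- nchar(as.character(plan$motif))
      if (any(plan$offset < 1L | plan$offset + k - 1L > length))
        stop("plant outside promoter for gene ", g)
      from <- length - plan$offset - k + 2L
      to <- length - plan$offset + 1L
      spans <- data.frame(from = from, to = to,
                          motif = as.character(plan$motif))
      o <- order(spans$from)
      if (any(spans$from[o][-1] <= spans$to[o][-nrow(spans)]))
        stop("overlapping planted motifs for gene ", g)
    }
    for (attempt in 1:100) {
      chars <- rep(NA_character_, length)
      fixed <- rep(FALSE, length)
      if (!is.null(spans)) {
        for (i in seq_len(nrow(spans))) {
          chars[spans$from[i]:spans$to[i]] <-
            strsplit(spans$motif[i], "")[[1]]
          fixed[spans$from[i]:spans$to[i]] <- TRUE
        }
      }
      chars <- .fillBackground(chars, fixed, avoidBoth, gc)
      seq <- paste(chars, collapse = "")
      # verify: every avoided-motif occurrence must be a planned plant
      okSeq <- TRUE
      for (mot in avoidMotifs) {
        hits <- .matchBoth(seq, mot)
        if (!is.null(spans))
          wanted <- spans$from[spans$motif == mot]
        else wanted <- integer(0)
        if (!setequal(hits$start, wanted) ||
            nrow(hits) != base::length(wanted)) {
          okSeq <- FALSE
          break
        }
      }
      if (okSeq) break
      if (attempt == 100)
        stop("could not build a clean background for gene ", g)
    }
    out[g] <- seq
  }
  Biostrings::DNAStringSet(out)
}

# all forward + reverse-complement occurrences of motif in a sequence
# string; palindromic motifs reported once (forward). Returns string
# coordinates (start/end, 1-based from the 5' end of the stored sequence).
.matchBoth <- function(seq, motif) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(motif, subj)
  res <- data.frame(start = BiocGenerics::start(fwd),
                    end = BiocGenerics::end(fwd),
                    strand = rep("+", base::length(fwd)),
                    stringsAsFactors = FALSE)
  rc <- .revcomp(motif)
  if (rc != motif) {
    rev <- Biostrings::matchPattern(rc, subj)
    res <- rbind(res, data.frame(start = BiocGenerics::start(rev),
                                 end = BiocGenerics::end(rev),
                                 strand = rep("-", base::length(rev)),
                                 stringsAsFactors = FALSE))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}
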