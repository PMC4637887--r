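#' @import methods
NULL

.SNP_COLS <- c("snp_id", "chrom", "pos", "ref", "alt", "gene_id",
               "maf", "counted", "monomorphic")

#' GenotypeMatrix: coded biallelic genotypes for a panel of individuals
#'
#' Stores genotype calls as counts of the minor allele (0, 1, 2 or \code{NA})
#' in an individuals-by-SNPs matrix, together with per-SNP metadata
#' (identifier, coordinates, alleles, gene annotation, minor allele
#' frequency). The minor allele is determined per site from the loaded
#' cohort, not from the VCF REF/ALT orientation, so additive effects are
#' oriented consistently across sites.
#'
#' @slot calls numeric matrix, individuals x SNPs, values in {0, 1, 2, NA};
#'   rownames are individual ids, colnames are SNP ids.
#' @slot snpData data.frame with one row per SNP: \code{snp_id},
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt},
#'   \code{gene_id}, \code{maf}, \code{counted} ("ref" or "alt": which VCF
#'   allele the codes count), \code{monomorphic} (flag; monomorphic SNPs are
#'   retained but association operations skip them).
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         slots = c(calls = "matrix", snpData = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  cl <- object@calls
  sd <- object@snpData
  if (!is.numeric(cl))
    msg <- c(msg, "calls must be a numeric matrix")
  bad <- cl[!is.na(cl)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (!all(.SNP_COLS %in% names(sd)))
    msg <- c(msg, paste("snpData must contain columns:",
                        paste(.SNP_COLS, collapse = ", ")))
  if (nrow(sd) != ncol(cl))
    msg <- c(msg, "snpData rows must match calls columns")
  if (is.null(rownames(cl)) || anyDuplicated(rownames(cl)))
    msg <- c(msg, "individual ids (rownames of calls) must be unique")
  if ("snp_id" %in% names(sd)) {
    if (anyDuplicated(sd$snp_id))
      msg <- c(msg, "snp ids must be unique")
    if (!is.null(colnames(cl)) && nrow(sd) &&
        !identical(colnames(cl), as.character(sd$snp_id)))
      msg <- c(msg, "colnames(calls) must equal snpData$snp_id")
  }
  if ("ref" %in% names(sd) && "alt" %in% names(sd) &&
      any(!is.na(sd$ref) & !is.na(sd$alt) & sd$ref == sd$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if ("pos" %in% names(sd) && any(!is.na(sd$pos) & sd$pos < 1))
    msg <- c(msg, "positions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric matrix of genotype codes (individuals x SNPs),
#'   values 0/1/2/NA counting the minor allele. Rownames are individual ids.
#' @param snpData data.frame of per-SNP metadata; missing \code{maf},
#'   \code{counted} and \code{monomorphic} columns are filled in
#'   (maf recomputed from \code{calls}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(calls, snpData) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(colnames(calls)) && "snp_id" %in% names(snpData))
    colnames(calls) <- as.character(snpData$snp_id)
  if (!"maf" %in% names(snpData))
    snpData$maf <- .mafFromCalls(calls)
  if (!"counted" %in% names(snpData))
    snpData$counted <- "alt"
  if (!"monomorphic" %in% names(snpData))
    snpData$monomorphic <- .mafFromCalls(calls) == 0
  for (col in c("gene_id", "chrom")) {
    if (!col %in% names(snpData)) snpData[[col]] <- NA_character_
  }
  if (!"pos" %in% names(snpData)) snpData$pos <- NA_integer_
  if (!"ref" %in% names(snpData)) snpData$ref <- NA_character_
  if (!"alt" %in% names(snpData)) snpData$alt <- NA_character_
  snpData <- snpData[, .SNP_COLS, drop = FALSE]
  rownames(snpData) <- NULL
  new("GenotypeMatrix", calls = calls, snpData = snpData)
}

# minor allele frequency from coded calls (complete-data columns exact)
.mafFromCalls <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  unname(f)
}

#' @describeIn genotypeMatrix genotype call matrix (individuals x SNPs)
#' @param x a GenotypeMatrix
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn genotypeMatrix per-SNP metadata data.frame
#' @export
snpInfo <- function(x) x@snpData

#' @describeIn genotypeMatrix individual identifiers
#' @export
individualIds <- function(x) rownames(x@calls)

#' @describeIn genotypeMatrix number of SNPs
#' @export
nSnps <- function(x) ncol(x@calls)

#' @describeIn genotypeMatrix number of individuals
#' @export
nIndividuals <- function(x) nrow(x@calls)

#' @describeIn genotypeMatrix subset by individuals and/or SNPs (ids or
#'   indices); returns a new GenotypeMatrix with maf recomputed
#' @param individuals,snps index or id vectors
#' @export
subsetGenotypes <- function(x, individuals = NULL, snps = NULL) {
  cl <- x@calls
  sd <- x@snpData
  if (!is.null(individuals)) cl <- cl[individuals, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, sd$snp_id)
    cl <- cl[, snps, drop = FALSE]
    sd <- sd[snps, , drop = FALSE]
  }
  sd$maf <- .mafFromCalls(cl)
  sd$monomorphic <- is.na(sd$maf) | sd$maf == 0
  genotypeMatrix(cl, sd)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "SNPs\n")
  ge <- unique(object@snpData$gene_id)
  cat("  genes:", length(ge[!is.na(ge)]),
      "| monomorphic SNPs:", sum(object@snpData$monomorphic),
      "| missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(object@calls))), "\n")
})

#' LayeredNetwork: hub-centered layered gene-gene interaction network
#'
#' Genes interacting directly with the hub occupy layer 2; genes reachable
#' from the hub only through other genes occupy layer 3 (by default the
#' depth is capped so all deeper reachable genes stay in the outermost
#' layer). Edges carry a class derived from their endpoint layers and the
#' list of supporting SNP-pair records.
#'
#' @slot hub hub gene identifier (the unique layer-1 member).
#' @slot layers named integer vector: gene -> layer.
#' @slot edges data.frame: \code{gene_a}, \code{gene_b}, \code{edge_class},
#'   \code{n_support}, \code{support} (";"-collapsed SNP pair ids),
#'   \code{traits} (";"-collapsed).
#' @slot unconnected genes present in the input edge list but unreachable
#'   from the hub (excluded from layers).
#'
#' @aliases LayeredNetwork-class
#' @exportClass LayeredNetwork
setClass("LayeredNetwork",
         slots = c(hub = "character", layers = "integer",
                   edges = "data.frame", unconnected = "character"))

setValidity("LayeredNetwork", function(object) {
  msg <- character(0)
  ly <- object@layers
  if (length(object@hub) != 1L)
    msg <- c(msg, "hub must be a single gene id")
  if (!object@hub %in% names(ly) || ly[[object@hub]] != 1L)
    msg <- c(msg, "hub must be in layers with layer 1")
  if (sum(ly == 1L) != 1L)
    msg <- c(msg, "hub must be the unique layer-1 member")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildLayers hub gene of a LayeredNetwork
#' @export
hubGene <- function(network) network@hub

#' @describeIn buildLayers named integer vector of layer assignments
#' @export
layerOf <- function(network) network@layers

#' @describeIn buildLayers edge table with classes and support
#' @export
networkEdges <- function(network) network@edges

#' @describeIn buildLayers genes excluded as unreachable from the hub
#' @export
unconnectedGenes <- function(network) network@unconnected

setMethod("show", "LayeredNetwork", function(object) {
  ly <- object@layers
  cat("LayeredNetwork around hub", object@hub, "\n")
  cat("  layer sizes:",
      paste(sprintf("L%d=%d", sort(unique(ly)), tabulate(ly)[sort(unique(ly))]),
            collapse = " "),
      "| edges:", nrow(object@edges),
      "| unconnected:", length(object@unconnected), "\n")
})

#' LdDecayFit: fitted expected-r2 decay curve
#'
#' Holds the scaled recombination parameter C of the Hill-Weir expectation
#' for r-squared as a function of physical distance, together with the
#' sample size used for the finite-sample correction.
#'
#' @slot C positive scalar; the fitted per-bp population recombination
#'   parameter (C * distance is the scaled distance of the curve).
#' @slot n sample size entering the finite-sample term.
#' @slot rss residual sum of squares at the optimum.
#' @slot nPairs number of SNP pairs used.
#' @slot boundary TRUE when the optimum ran into the lower search bound
#'   (curve effectively flat, e.g. all r2 equal to 1).
#'
#' @aliases LdDecayFit-class
#' @exportClass LdDecayFit
setClass("LdDecayFit",
         slots = c(C = "numeric", n = "integer", rss = "numeric",
                   nPairs = "integer", boundary = "logical"))

#' Construct an LdDecayFit
#'
#' Mostly used internally by \code{\link{fitLdDecay}}; exposed so decay
#' curves with a known C can be built directly (e.g. for plotting or
#' crossing-distance calculations).
#'
#' @param C positive per-bp recombination parameter.
#' @param n sample size.
#' @param rss residual sum of squares (default NA for hand-built curves).
#' @param nPairs number of pairs behind the fit.
#' @param boundary whether the fit hit the flat-curve boundary.
#' @return An \linkS4class{LdDecayFit}.
#' @export
ldDecayFit <- function(C, n, rss = NA_real_, nPairs = 0L,
                       boundary = FALSE) {
  obj <- new("LdDecayFit")
  obj@C <- C
  obj@n <- as.integer(n)
  obj@rss <- rss
  obj@nPairs <- as.integer(nPairs)
  obj@boundary <- boundary
  obj
}

#' @describeIn ldDecayFit fitted per-bp recombination parameter C
#' @param fit an LdDecayFit
#' @export
ldDecayC <- function(fit) fit@C

setMethod("show", "LdDecayFit", function(object) {
  cat(sprintf("LdDecayFit: C = %.6g (n = %d, pairs = %d, rss = %.4g)%s\n",
              object@C, object@n, object@nPairs, object@rss,
              if (object@boundary) " [boundary]" else ""))
})

#' EffectModel: generative genetic architecture for phenotype simulation
#'
#' @slot mu grand mean (trait units).
#' @slot additive named numeric: snp_id -> a, trait units per minor-allele
#'   copy (half the homozygote difference).
#' @slot dominance named numeric: snp_id -> d (heterozygote deviation from
#'   the homozygote midpoint).
#' @slot epistasis data.frame with columns \code{snp1}, \code{snp2},
#'   \code{type} (AxA, AxD, DxA, DxD), \code{coef}.
#' @slot structureEffects numeric vector of fixed effects over Q columns.
#' @slot sigma residual standard deviation (> 0, or 0 for noiseless checks).
#'
#' @aliases EffectModel-class
#' @exportClass EffectModel
setClass("EffectModel",
         slots = c(mu = "numeric", additive = "numeric", dominance = "numeric",
                   epistasis = "data.frame", structureEffects = "numeric",
                   sigma = "numeric"))

setValidity("EffectModel", function(object) {
  msg <- character(0)
  if (length(object@sigma) != 1L || object@sigma < 0)
    msg <- c(msg, "sigma must be a single value >= 0")
  if (nrow(object@epistasis)) {
    need <- c("snp1", "snp2", "type", "coef")
    if (!all(need %in% names(object@epistasis)))
      msg <- c(msg, "epistasis needs columns snp1, snp2, type, coef")
    else if (!all(object@epistasis$type %in% c("AxA", "AxD", "DxA", "DxD")))
      msg <- c(msg, "epistasis type must be AxA, AxD, DxA or DxD")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EffectModel
#'
#' @param mu grand mean.
#' @param additive,dominance named numeric vectors keyed by snp_id.
#' @param epistasis data.frame(snp1, snp2, type, coef); types among
#'   AxA, AxD, DxA, DxD.
#' @param structureEffects numeric vector over Q-matrix columns.
#' @param sigma residual SD.
#' @return An \linkS4class{EffectModel}.
#' @export
effectModel <- function(mu = 0, additive = numeric(0), dominance = numeric(0),
                        epistasis = NULL, structureEffects = numeric(0),
                        sigma = 1) {
  if (is.null(epistasis))
    epistasis <- data.frame(snp1 = character(0), snp2 = character(0),
                            type = character(0), coef = numeric(0))
  new("EffectModel", mu = mu, additive = additive, dominance = dominance,
      epistasis = epistasis, structureEffects = structureEffects,
      sigma = sigma)
}

#' SimulationSpec: parameters of the synthetic genotype panel
#'
#' @slot nIndividuals panel size.
#' @slot nSnps number of biallelic SNPs.
#' @slot maf per-SNP minor allele frequency, recycled to nSnps.
#' @slot mafRange optional length-2 range; when set, per-SNP MAFs are drawn
#'   uniformly from it (overrides \code{maf}).
#' @slot ldBlocks list of \code{list(snps = <indices>, rho = <copy prob>)};
#'   within a block every SNP copies the anchor's haplotypes with
#'   probability rho per haplotype.
#' @slot geneAssignment character vector of gene ids, recycled to nSnps.
#' @slot positions 1-based bp positions (default: 24-bp spacing, matching a
#'   dense candidate-gene panel).
#' @slot chrom chromosome label(s).
#' @slot seed RNG seed.
#'
#' @aliases SimulationSpec-class
#' @exportClass SimulationSpec
setClass("SimulationSpec",
         slots = c(nIndividuals = "integer", nSnps = "integer",
                   maf = "numeric", mafRange = "numeric",
                   ldBlocks = "list", geneAssignment = "character",
                   positions = "integer", chrom = "character",
                   seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (any(object@maf <= 0 | object@maf > 0.5))
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (length(object@mafRange) &&
      (length(object@mafRange) != 2L ||
       any(object@mafRange <= 0 | object@mafRange > 0.5)))
    msg <- c(msg, "mafRange must be two values in (0, 0.5]")
  for (b in object@ldBlocks) {
    if (!all(c("snps", "rho") %in% names(b)) ||
        b$rho < 0 || b$rho > 1 ||
        any(b$snps < 1 | b$snps > object@nSnps))
      msg <- c(msg, "each ldBlock needs valid snps and rho in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' @param nIndividuals,nSnps panel dimensions.
#' @param maf scalar or per-SNP minor allele frequencies in (0, 0.5].
#' @param mafRange optional c(lo, hi); per-SNP MAF drawn uniformly.
#' @param ldBlocks list of list(snps=, rho=) haplotype-copy blocks.
#' @param geneAssignment gene id per SNP (recycled).
#' @param positions bp positions (default 24-bp spacing).
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(nIndividuals, nSnps, maf = 0.3,
                           mafRange = numeric(0), ldBlocks = list(),
                           geneAssignment = "gene1", positions = NULL,
                           chrom = "chr1", seed = 1L) {
  if (is.null(positions)) positions <- seq_len(nSnps) * 24L
  new("SimulationSpec",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      maf = rep_len(as.numeric(maf), nSnps), mafRange = as.numeric(mafRange),
      ldBlocks = ldBlocks,
      geneAssignment = rep_len(as.character(geneAssignment), nSnps),
      positions = as.integer(rep_len(positions, nSnps)),
      chrom = rep_len(as.character(chrom), nSnps),
      seed = as.integer(seed))
}
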