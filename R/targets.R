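#' Scan promoters for exact motif occurrences
#'
#' Reports every exact occurrence (overlaps included) of each motif in
#' each promoter. In \code{"both"} mode, occurrences of the reverse
#' complement are reported on strand "-"; a motif that is its own reverse
#' complement (e.g. TCACGTGA) is reported once, on the forward strand.
#' The hit position \code{upstream_start} is the upstream offset (bp, 1 =
#' immediately 5' of the TSS) of the motif base closest to the TSS.
#'
#' @param promoters named \code{DNAStringSet} (or named character vector).
#' @param motifs character vector of motifs over A/C/G/T (defaults: the
#'   WUS-box TCACGTGA and its alternative core TAAT).
#' @param strandMode \code{"both"} (default) or \code{"forward"}.
#' @return data.frame(gene_id, motif, upstream_start, strand), one row per
#'   hit, ordered by gene, motif, position. Genes shorter than a motif are
#'   skipped for that motif with a warning.
#' @export
scanMotifs <- function(promoters, motifs = c("TCACGTGA", "TAAT"),
                       strandMode = c("both", "forward")) {
  strandMode <- match.arg(strandMode)
  if (is(promoters, "DNAStringSet")) promoters <- as.character(promoters)
  if (is.null(names(promoters))) stop("promoters must be named by gene id")
  if (any(!grepl("^[ACGT]+$", motifs)))
    stop("motifs must be over A/C/G/T")
  rows <- list()
  for (g in names(promoters)) {
    seq <- promoters[[g]]
    L <- nchar(seq)
    for (mot in motifs) {
      if (nchar(mot) > L) {
        warning("promoter of ", g, " shorter than motif ", mot,
                "; gene skipped for this motif")
        next
      }
      hits <- if (strandMode == "both") .matchBoth(seq, mot)
      else {
        subj <- Biostrings::DNAString(seq)
        m <- Biostrings::matchPattern(mot, subj)
        data.frame(start = BiocGenerics::start(m),
                   end = BiocGenerics::end(m),
                   strand = rep("+", length(m)), stringsAsFactors = FALSE)
      }
      if (nrow(hits))
        rows[[base::length(rows) + 1L]] <- data.frame(
          gene_id = g, motif = mot,
          upstream_start = L - hits$end + 1L,
          strand = hits$strand, stringsAsFactors = FALSE)
    }
  }
  if (!base::length(rows))
    return(data.frame(gene_id = character(0), motif = character(0),
                      upstream_start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$motif, out$upstream_start), ]
  rownames(out) <- NULL
  out
}

#' Positional distribution of motif hits over upstream windows
#'
#' Windows are closed intervals in bp upstream of the TSS. Each window's
#' value is the fraction of all hits falling inside it; hits outside every
#' window stay in the denominator, so fractions sum to at most 1 (and to
#' exactly 1 when the windows tile the promoter).
#'
#' @param hits data.frame from \code{\link{scanMotifs}}.
#' @param windows list of c(lo, hi) pairs, non-overlapping; defaults to the
#'   two windows highlighted in the study design (300-600, 650-950).
#' @return named numeric vector of fractions ("lo-hi" names). All-NA with
#'   a warning when there are no hits.
#' @export
motifWindowFractions <- function(hits,
                                 windows = list(c(300, 600), c(650, 950))) {
  lo <- vapply(windows, `[`, numeric(1), 1)
  hi <- vapply(windows, `[`, numeric(1), 2)
  if (any(hi < lo)) stop("each window must be c(lo, hi) with lo <= hi")
  o <- order(lo)
  if (any(lo[o][-1] <= hi[o][-length(o)]))
    stop("windows must be non-overlapping")
  nm <- paste0(lo, "-", hi)
  if (!nrow(hits)) {
    warning("no hits: window fractions undefined")
    return(stats::setNames(rep(NA_real_, length(windows)), nm))
  }
  total <- nrow(hits)
  frac <- vapply(seq_along(windows), function(i)
    sum(hits$upstream_start >= lo[i] & hits$upstream_start <= hi[i]) / total,
    numeric(1))
  stats::setNames(frac, nm)
}

#' Pearson correlation of every gene's expression with a hub gene
#'
#' @param expr numeric matrix genes x conditions (>= 3 conditions).
#' @param hubGene row name of the hub; its profile must not be constant.
#' @return named numeric vector of Pearson r for all genes except the hub;
#'   genes with constant profiles are excluded with a warning.
#' @export
expressionCorrelation <- function(expr, hubGene) {
  if (!hubGene %in% rownames(expr)) stop("hub gene ", hubGene, " not in matrix")
  if (ncol(expr) < 3L) stop("need at least 3 conditions")
  hub <- expr[hubGene, ]
  if (stats::sd(hub) == 0) stop("hub profile is constant")
  others <- setdiff(rownames(expr), hubGene)
  sds <- apply(expr[others, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant expression profile(s) excluded: ",
            paste(others[sds == 0], collapse = ", "))
    others <- others[sds > 0]
  }
  vapply(others, function(g) stats::cor(expr[g, ], hub),
         numeric(1))
}

#' Differential-expression threshold screen
#'
#' Keeps genes whose supplied DE statistics pass the fold-change and
#' significance cutoffs: FC >= fcUp or FC <= fcDown (both inclusive), and
#' q <= qMax and p <= pMax.
#'
#' @param rows data.frame(gene_id, fold_change, p_value, q_value).
#' @param fcUp,fcDown,qMax,pMax thresholds; defaults 2, 0.5, 0.10, 1e-3.
#' @return character vector of retained gene ids.
#' @export
screenDE <- function(rows, fcUp = 2, fcDown = 0.5, qMax = 0.10,
                     pMax = 1e-3) {
  stopifnot(fcUp > 0, fcDown > 0, qMax >= 0, qMax <= 1, pMax >= 0, pMax <= 1)
  if (any(rows$fold_change <= 0)) stop("fold changes must be positive")
  keep <- (rows$fold_change >= fcUp | rows$fold_change <= fcDown) &
    rows$q_value <= qMax & rows$p_value <= pMax
  rows$gene_id[keep]
}

#' Call putative hub targets from motif presence and co-expression
#'
#' A gene is selected as a target when its promoter carries at least one
#' motif hit and its expression correlation with the hub is strictly
#' beyond the threshold (|r| > rThreshold; r exactly at the threshold is
#' excluded). Direction records the sign of r for selected genes.
#'
#' @param hits data.frame from \code{\link{scanMotifs}}.
#' @param correlations named numeric from
#'   \code{\link{expressionCorrelation}}.
#' @param rThreshold strict absolute-correlation cutoff (default 0.8).
#' @param requireMotif one of the scanned motifs to require specifically,
#'   or NULL (default) to accept any motif hit.
#' @return data.frame(gene_id, has_motif, pearson_r, direction, selected),
#'   one row per gene in the union of both inputs, sorted by gene id.
#' @export
selectTargets <- function(hits, correlations, rThreshold = 0.8,
                          requireMotif = NULL) {
  stopifnot(rThreshold >= 0, rThreshold <= 1)
  if (!is.null(requireMotif)) hits <- hits[hits$motif == requireMotif, ]
  genes <- sort(union(unique(hits$gene_id), names(correlations)))
  hasMotif <- genes %in% hits$gene_id
  r <- unname(correlations[genes])
  selected <- hasMotif & !is.na(r) & abs(r) > rThreshold
  direction <- ifelse(selected, ifelse(r > 0, "positive", "negative"),
                      "none")
  data.frame(gene_id = genes, has_motif = hasMotif, pearson_r = r,
             direction = direction, selected = selected,
             stringsAsFactors = FALSE)
}
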