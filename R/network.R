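#' Collapse significant SNP pairs to gene-level edges
#'
#' All significant SNP pairs connecting two distinct genes collapse to a
#' single undirected gene edge carrying the supporting SNP-pair records
#' and the traits involved. Within-gene SNP pairs are dropped (a gene is
#' never its own edge); records with a missing gene annotation are
#' skipped with a warning.
#'
#' @param sigPairs data.frame with columns \code{gene1}, \code{gene2},
#'   \code{snp_id1}, \code{snp_id2} and optionally \code{trait} (typically
#'   the significant subset of a \code{\link{scanEpistasis}} result).
#' @return data.frame(gene_a, gene_b, n_support, support, traits) with
#'   gene_a < gene_b, sorted.
#' @export
collapseToGeneEdges <- function(sigPairs) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      n_support = integer(0), support = character(0),
                      traits = character(0), stringsAsFactors = FALSE)
  if (!nrow(sigPairs)) return(empty)
  miss <- is.na(sigPairs$gene1) | is.na(sigPairs$gene2)
  if (any(miss)) {
    warning(sum(miss), " record(s) without gene annotation skipped")
    sigPairs <- sigPairs[!miss, , drop = FALSE]
  }
  sigPairs <- sigPairs[sigPairs$gene1 != sigPairs$gene2, , drop = FALSE]
  if (!nrow(sigPairs)) return(empty)
  a <- pmin(sigPairs$gene1, sigPairs$gene2)
  b <- pmax(sigPairs$gene1, sigPairs$gene2)
  key <- paste(a, b, sep = "\r")
  sup <- paste(sigPairs$snp_id1, sigPairs$snp_id2, sep = "|")
  tr <- if ("trait" %in% names(sigPairs)) sigPairs$trait
        else rep(NA_character_, nrow(sigPairs))
  agg <- lapply(split(seq_along(key), key), function(ix) {
    us <- sort(unique(sup[ix]))
    data.frame(gene_a = a[ix[1]], gene_b = b[ix[1]],
               n_support = length(us),
               support = paste(us, collapse = ";"),
               traits = paste(sort(unique(stats::na.omit(tr[ix]))),
                              collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' Build the hub-centered layered network
#'
#' Layer 1 is the hub alone; layer 2 contains the genes sharing an edge
#' with the hub; genes reachable from the hub only indirectly go to layer
#' 3 (or deeper, up to \code{maxLayer}; reachable genes beyond the cap
#' stay in the outermost layer). Genes in the edge list but unreachable
#' from the hub are excluded and reported separately. Edge classes are a
#' function of the endpoint layers only (e.g. "L1-L2", "within-L2",
#' "L2-L3", "within-L3"); construction is order-independent with
#' lexicographic tie-breaks.
#'
#' @param geneEdges data.frame from \code{\link{collapseToGeneEdges}} (or
#'   any data.frame whose first two columns are gene ids).
#' @param hub hub gene id; it need not occur in the edge list (then the
#'   network is the hub alone).
#' @param maxLayer outermost layer index (default 3).
#' @return a \linkS4class{LayeredNetwork}.
#' @export
buildLayers <- function(geneEdges, hub, maxLayer = 3L) {
  if (missing(hub) || is.null(hub) || is.na(hub) || !nzchar(hub))
    stop("hub gene must be declared")
  ga <- as.character(geneEdges[[1]])
  gb <- as.character(geneEdges[[2]])
  genes <- sort(unique(c(hub, ga, gb)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ga, to = gb, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  dist <- as.numeric(igraph::distances(g, v = hub)[1, ])
  names(dist) <- igraph::V(g)$name
  reachable <- names(dist)[is.finite(dist)]
  layers <- pmin(dist[reachable] + 1, maxLayer)
  layers <- stats::setNames(as.integer(layers), reachable)
  layers <- layers[order(names(layers))]
  unconnected <- sort(setdiff(genes, reachable))
  keep <- ga %in% reachable & gb %in% reachable
  ea <- pmin(ga[keep], gb[keep]); eb <- pmax(ga[keep], gb[keep])
  la <- layers[ea]; lb <- layers[eb]
  lo <- pmin(la, lb); hi <- pmax(la, lb)
  cls <- ifelse(lo == hi, paste0("within-L", lo),
                paste0("L", lo, "-L", hi))
  edges <- data.frame(gene_a = ea, gene_b = eb, edge_class = cls,
                      stringsAsFactors = FALSE)
  extra <- geneEdges[keep, setdiff(names(geneEdges),
                                   names(geneEdges)[1:2]), drop = FALSE]
  if (ncol(extra)) edges <- cbind(edges, extra)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("LayeredNetwork", hub = hub, layers = layers, edges = edges,
      unconnected = unconnected)
}

#' Fraction of a gene universe connected to the hub
#'
#' @param network a \linkS4class{LayeredNetwork}.
#' @param geneUniverse character vector of candidate genes (e.g. the
#'   selected targets); the hub is excluded from both numerator and
#'   denominator.
#' @return list(n_genes_in_network, n_universe, fraction_connected).
#' @export
connectivityFraction <- function(network, geneUniverse) {
  universe <- setdiff(unique(geneUniverse), network@hub)
  if (!length(universe)) stop("empty gene universe")
  inNet <- names(network@layers)[network@layers >= 2L]
  nIn <- length(intersect(universe, inNet))
  list(n_genes_in_network = nIn, n_universe = length(universe),
       fraction_connected = nIn / length(universe))
}

#' Export a layered network to SIF, GraphML or TSV
#'
#' SIF lines read "geneA interacts geneB"; GraphML carries the layer as a
#' vertex attribute and the edge class as an edge attribute (readable
#' back with igraph); TSV is the edge table with a header. Output
#' ordering is deterministic.
#'
#' @param network a \linkS4class{LayeredNetwork}.
#' @param path output file.
#' @param format "SIF", "GraphML" or "TSV".
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  e <- network@edges
  if (format == "SIF") {
    writeLines(if (nrow(e)) paste(e$gene_a, "interacts", e$gene_b)
               else character(0), path)
  } else if (format == "TSV") {
    .writeTsvFile(e, path)
  } else {
    genes <- names(network@layers)
    g <- igraph::graph_from_data_frame(
      if (nrow(e)) data.frame(from = e$gene_a, to = e$gene_b,
                              edge_class = e$edge_class,
                              stringsAsFactors = FALSE)
      else data.frame(from = character(0), to = character(0),
                      edge_class = character(0)),
      directed = FALSE,
      vertices = data.frame(name = genes,
                            layer = as.integer(network@layers),
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
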