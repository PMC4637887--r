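sigRow <- function(g1, s1, g2, s2, trait = "tr") {
  data.frame(snp_id1 = s1, gene1 = g1, snp_id2 = s2, gene2 = g2,
             trait = trait, stringsAsFactors = FALSE)
}

test_that("SNP pairs collapse to unique gene edges with support", {
  pairs <- rbind(sigRow("gA", "gA-SNP1", "gB", "gB-SNP1"),
                 sigRow("gA", "gA-SNP2", "gB", "gB-SNP2"),
                 sigRow("gA", "gA-SNP3", "gB", "gB-SNP3", trait = "t2"),
                 sigRow("gB", "gB-SNP4", "gA", "gA-SNP4"),  # reversed order
                 sigRow("gA", "gA-SNP5", "gB", "gB-SNP5"),
                 sigRow("gA", "gA-SNP1", "gA", "gA-SNP2"))  # within-gene
  edges <- collapseToGeneEdges(pairs)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$n_support, 5L)
  expect_equal(edges$traits, "t2;tr")
  expect_equal(nrow(collapseToGeneEdges(pairs[0, ])), 0L)
  pairs$gene2[2] <- NA
  expect_warning(e2 <- collapseToGeneEdges(pairs), "without gene annotation")
  expect_equal(e2$n_support, 4L)
})

test_that("layer assignment follows hub distance with a depth cap", {
  star <- data.frame(gene_a = "hub", gene_b = c("A", "B", "C"))
  net <- buildLayers(star, "hub")
  expect_equal(unname(layerOf(net)[c("A", "B", "C")]), c(2L, 2L, 2L))
  expect_equal(unname(layerOf(net)["hub"]), 1L)
  expect_equal(sort(unique(networkEdges(net)$edge_class)), "L1-L2")

  chain <- data.frame(gene_a = c("hub", "A", "B", "D"),
                      gene_b = c("A", "B", "C", "E"))  # D-E disconnected
  net <- buildLayers(chain, "hub")
  ly <- layerOf(net)
  expect_equal(unname(ly[c("A", "B", "C")]), c(2L, 3L, 3L))
  expect_setequal(unconnectedGenes(net), c("D", "E"))
  e <- networkEdges(net)
  expect_equal(e$edge_class[e$gene_a == "A" & e$gene_b == "B"], "L2-L3")
  expect_equal(e$edge_class[e$gene_a == "B" & e$gene_b == "C"], "within-L3")
  # no edge touches the hub except L1-L2
  hubEdges <- e[e$gene_a == "hub" | e$gene_b == "hub", ]
  expect_true(all(hubEdges$edge_class == "L1-L2"))

  expect_error(buildLayers(star, ""), "declared")
  lonely <- buildLayers(star[0, ], "hub")
  expect_equal(names(layerOf(lonely)), "hub")
})

test_that("layers equal BFS distance from the hub on random graphs", {
  set.seed(404)
  for (i in 1:200) {
    nGenes <- sample(4:14, 1)
    genes <- c("hub", paste0("g", seq_len(nGenes)))
    nEdges <- sample(3:20, 1)
    edges <- unique(data.frame(
      gene_a = sample(genes, nEdges, replace = TRUE),
      gene_b = sample(genes, nEdges, replace = TRUE)))
    edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
    if (!nrow(edges)) next
    net <- buildLayers(edges, "hub", maxLayer = 99L)
    dist <- oracle_bfs(edges, "hub")
    expect_setequal(names(layerOf(net)), names(dist))
    expect_equal(unname(layerOf(net)[names(dist)]),
                 unname(as.integer(dist + 1)))
  }
})

test_that("network construction is order independent", {
  set.seed(17)
  edges <- data.frame(gene_a = c("hub", "hub", "A", "B", "C", "D"),
                      gene_b = c("A", "B", "C", "C", "D", "E"))
  net1 <- buildLayers(edges, "hub")
  net2 <- buildLayers(edges[sample(nrow(edges)), ], "hub")
  expect_identical(layerOf(net1), layerOf(net2))
  expect_identical(networkEdges(net1), networkEdges(net2))
})

test_that("connectivity fraction counts universe genes in layers 2+", {
  edges <- data.frame(gene_a = "hub", gene_b = paste0("t", 1:40))
  net <- buildLayers(edges, "hub")
  universe <- paste0("t", 1:53)
  conn <- connectivityFraction(net, universe)
  expect_equal(conn$n_genes_in_network, 40L)
  expect_equal(conn$fraction_connected, 40 / 53)
  expect_equal(round(conn$fraction_connected, 3), 0.755)
  expect_equal(connectivityFraction(net, paste0("t", 1:40))$fraction_connected,
               1)
  expect_equal(connectivityFraction(net, paste0("x", 1:5))$fraction_connected,
               0)
  expect_error(connectivityFraction(net, "hub"), "empty")
})

test_that("exports are deterministic and GraphML round-trips attributes", {
  edges <- data.frame(gene_a = c("hub", "A"), gene_b = c("A", "B"))
  net <- buildLayers(edges, "hub")
  sif <- tempfile(fileext = ".sif")
  exportNetwork(net, sif, "SIF")
  expect_equal(readLines(sif), c("A interacts B", "A interacts hub"))

  gml <- tempfile(fileext = ".graphml")
  exportNetwork(net, gml, "GraphML")
  g <- igraph::read_graph(gml, format = "graphml")
  got <- stats::setNames(igraph::V(g)$layer, igraph::V(g)$name)
  expect_equal(got[names(layerOf(net))], stats::setNames(
    as.integer(layerOf(net)), names(layerOf(net))))
  expect_setequal(igraph::E(g)$edge_class, c("L1-L2", "L2-L3"))

  tsv <- tempfile(fileext = ".tsv")
  empty <- buildLayers(edges[0, ], "hub")
  exportNetwork(empty, tsv, "TSV")
  expect_equal(length(readLines(tsv)), 1L)  # header only
  expect_error(exportNetwork(net, tsv, "DOT"))
})
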