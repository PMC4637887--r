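test_that("two-locus design columns follow the coding table", {
  d <- twoLocusDesign(c(2, 1, 0), c(0, 1, 0))
  # individual (2, 0)
  expect_equal(unlist(d[1, ]), c(x1 = 1, z1 = -0.5, x2 = -1, z2 = -0.5,
                                 x1x2 = -1, x1z2 = -0.5, z1x2 = 0.5,
                                 z1z2 = 0.25))
  # individual (1, 1): all additive products vanish
  expect_equal(unlist(d[2, ]), c(x1 = 0, z1 = 0.5, x2 = 0, z2 = 0.5,
                                 x1x2 = 0, x1z2 = 0, z1x2 = 0, z1z2 = 0.25))
  cells <- attr(twoLocusDesign(rep(0, 7), rep(0, 7)), "cells")
  expect_equal(as.integer(cells["0", "0"]), 7L)
  expect_equal(sum(cells), 7L)
})

test_that("centered design columns are orthogonal under balanced counts", {
  # the orthogonal-contrast structure behind the decomposition: with every
  # 3x3 cell equally occupied, the mean-centered single-locus codes and the
  # products of centered codes form a mutually orthogonal design
  g1 <- rep(0:2, each = 9)
  g2 <- rep(rep(0:2, each = 3), 3)
  X <- as.matrix(twoLocusDesign(g1, g2))
  ctr <- function(v) v - mean(v)
  Xc <- cbind(x1 = ctr(X[, "x1"]), z1 = ctr(X[, "z1"]),
              x2 = ctr(X[, "x2"]), z2 = ctr(X[, "z2"]),
              x1x2 = ctr(X[, "x1"]) * ctr(X[, "x2"]),
              x1z2 = ctr(X[, "x1"]) * ctr(X[, "z2"]),
              z1x2 = ctr(X[, "z1"]) * ctr(X[, "x2"]),
              z1z2 = ctr(X[, "z1"]) * ctr(X[, "z2"]))
  G <- crossprod(Xc)
  offDiag <- G - diag(diag(G))
  expect_true(all(abs(offDiag) < 1e-12))
  expect_true(all(abs(colMeans(Xc)) < 1e-12))
})

test_that("epistasis p-values match the lm full-vs-reduced oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 120
    g1 <- random_panel(n, 0.4)
    g2 <- random_panel(n, 0.3)
    Q <- cbind(q = stats::runif(n))
    y <- as.numeric(1 + 0.3 * (g1 - 1) - 0.2 * (g2 - 1) +
                      0.5 * (g1 - 1) * (g2 - 1) + Q[, 1] + stats::rnorm(n))
    mine <- epistasisTest(y, g1, g2, Q)
    orc <- oracle_epistasis(y, g1, g2, Q)
    for (ty in c("AxA", "AxD", "DxA", "DxD"))
      expect_equal(mine$effects$p[mine$effects$type == ty], orc[[ty]],
                   tolerance = 1e-10)
    expect_equal(mine$pair_p, orc$joint, tolerance = 1e-10)
  }
})

test_that("a pure AxA architecture is recovered exactly at sigma -> 0", {
  g <- simulateGenotypes(simulationSpec(600, 2, maf = 0.5, seed = 41))
  snp <- snpInfo(g)$snp_id
  m <- effectModel(mu = 10, epistasis = data.frame(
    snp1 = snp[1], snp2 = snp[2], type = "AxA", coef = 1), sigma = 0)
  y <- simulatePhenotype(g, m, seed = 6)$trait
  cl <- genotypeCalls(g)
  res <- epistasisTest(y, cl[, 1], cl[, 2])
  est <- stats::setNames(res$effects$estimate, res$effects$type)
  expect_equal(unname(est["AxA"]), 1, tolerance = 1e-8)
  expect_true(all(abs(est[c("AxD", "DxA", "DxD")]) < 1e-8))
})

test_that("a duplicated SNP yields non-estimable flags, not a crash", {
  set.seed(5)
  g1 <- random_panel(100, 0.4)
  y <- stats::rnorm(100)
  res <- epistasisTest(y, g1, g1, minCells = 3)
  expect_equal(res$reason, "non_estimable_effects")
  expect_true(any(is.na(res$effects$estimate)))
  # under the default occupancy rule the diagonal-only table is skipped
  expect_equal(epistasisTest(y, g1, g1)$reason, "too_few_occupied_cells")
})

test_that("occupancy rule skips sparse pairs with a reason", {
  g1 <- c(rep(0, 30), rep(1, 30), rep(2, 2))   # minor homozygotes too rare
  g2 <- rep(0:2, length.out = 62)
  res <- epistasisTest(stats::rnorm(62), g1, g2, minMarginal = 3)
  expect_equal(res$status, "skipped")
  expect_equal(res$reason, "marginal_class_below_minimum")
})

test_that("combination effects equal the per-individual enumeration oracle", {
  set.seed(13)
  g1 <- random_panel(20, 0.4)
  g2 <- random_panel(20, 0.35)
  y <- stats::rnorm(20, 10)
  mine <- combinationEffects(y, g1, g2, "AxA", c("A", "T"), c("C", "G"))
  orc <- oracle_combo_axa(y, g1, g2, c("A", "T"), c("C", "G"))
  orc <- orc[match(mine$combo, orc$combo), ]
  expect_equal(mine$effect, orc$effect, tolerance = 1e-12)
  expect_equal(mine$frequency, orc$frequency, tolerance = 1e-12)
  # rows sorted by effect, descending
  expect_true(all(diff(mine$effect) <= 0))
})

test_that("combination frequencies sum to 1 and AxA effects are centered", {
  set.seed(29)
  g1 <- random_panel(200, 0.45)
  g2 <- random_panel(200, 0.25)
  y <- stats::rnorm(200, 40, 2)
  for (ty in c("AxA", "AxD", "DxA", "DxD")) {
    tab <- combinationEffects(y, g1, g2, ty)
    expect_equal(sum(tab$frequency), 1, tolerance = 1e-12)
    expect_equal(sum(tab$frequency * tab$effect), 0, tolerance = 1e-9)
  }
  # two loci fixed heterozygous: a single DxD combination, effect zero
  oneCell <- combinationEffects(rep(3, 10), rep(1, 10), rep(1, 10), "DxD",
                                c("A", "T"), c("C", "G"))
  expect_equal(nrow(oneCell), 1L)
  expect_equal(oneCell$combo, "AT-CG")
  expect_equal(oneCell$effect, 0)
  expect_equal(oneCell$frequency, 1)
})

test_that("combination deviations are raw cell means about the grand mean", {
  y <- c(10, 12, 20, 22, 30)
  g1 <- c(0, 0, 1, 1, 2)
  g2 <- c(0, 0, 1, 1, 2)
  m <- combinationDeviations(y, g1, g2)
  expect_equal(m["0", "0"], 11 - mean(y))
  expect_equal(m["1", "1"], 21 - mean(y))
  expect_equal(m["2", "2"], 30 - mean(y))
  expect_true(is.na(m["0", "2"]))
  # constant trait: all occupied cells at zero deviation
  m0 <- combinationDeviations(rep(4, 5), g1, g2)
  expect_true(all(m0[!is.na(m0)] == 0))
})

test_that("hub-target pair enumeration is the full cross product", {
  calls <- matrix(rep(c(0, 1, 2), 119 * 4), nrow = 12)
  rownames(calls) <- sprintf("i%02d", 1:12)
  sd_ <- data.frame(snp_id = c(sprintf("HUB-SNP%d", 1:19),
                               sprintf("T%03d-SNP1", 1:100)),
                    gene_id = c(rep("HUB", 19), sprintf("T%03d", 1:100)))
  g <- genotypeMatrix(calls, sd_)
  pairs <- hubTargetPairs(g, "HUB")
  expect_equal(nrow(pairs), 19L * 100L)
  expect_true(all(grepl("^HUB", pairs[, 1])))
})

test_that("the epistasis scan flags a planted pair and honors BH families", {
  g <- simulateGenotypes(simulationSpec(435, 12, maf = 0.4,
                                        geneAssignment = rep(c("HUB", "T1",
                                                               "T2", "T3"),
                                                             each = 3),
                                        seed = 77))
  snp <- snpInfo(g)$snp_id
  m <- effectModel(mu = 0, epistasis = data.frame(
    snp1 = "HUB-SNP1", snp2 = "T1-SNP1", type = "AxA", coef = 0.6),
    sigma = 1)
  ph <- simulatePhenotype(g, m, seed = 8, traitName = "tr")
  res <- scanEpistasis(g, ph, hubTargetPairs(g, "HUB"))
  hit <- res[res$snp_id1 == "HUB-SNP1" & res$snp_id2 == "T1-SNP1" &
               res$effect_type == "AxA", ]
  expect_true(hit$significant)
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
})
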