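test_that("identical spec and seed give bit-identical outputs", {
  spec <- simulationSpec(50, 10, mafRange = c(0.1, 0.5),
                         ldBlocks = list(list(snps = 1:3, rho = 0.8)),
                         seed = 99)
  g1 <- simulateGenotypes(spec)
  g2 <- simulateGenotypes(spec)
  expect_identical(genotypeCalls(g1), genotypeCalls(g2))
  m <- effectModel(mu = 5, additive = c("gene1-SNP1" = 0.4), sigma = 1)
  expect_identical(simulatePhenotype(g1, m, seed = 3),
                   simulatePhenotype(g2, m, seed = 3))
  e1 <- simulateExpression(c("a", "b"), "hub", c(a = 0.9), seed = 4)
  e2 <- simulateExpression(c("a", "b"), "hub", c(a = 0.9), seed = 4)
  expect_identical(e1, e2)
  plan <- list(a = data.frame(motif = "TCACGTGA", offset = 300L))
  expect_identical(as.character(plantPromoters(plan, length = 600, seed = 7)),
                   as.character(plantPromoters(plan, length = 600, seed = 7)))
})

test_that("genotypes follow HWE frequencies at the requested MAF", {
  n <- 10000
  g <- simulateGenotypes(simulationSpec(n, 1, maf = 0.5, seed = 123))
  counts <- tabulate(genotypeCalls(g)[, 1] + 1, 3)
  expected <- n * c(0.25, 0.5, 0.25)
  sds <- sqrt(n * c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("HWE goodness of fit is rarely rejected across replicate panels", {
  # chi-square GOF at alpha = 0.001 should pass in >= 99% of panels
  reject <- vapply(1:400, function(s) {
    g <- simulateGenotypes(simulationSpec(1000, 1, maf = 0.3, seed = s))
    x <- genotypeCalls(g)[, 1]
    p <- mean(x) / 2
    exp_ <- 1000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(x + 1, 3)
    stat <- sum((obs - exp_)^2 / pmax(exp_, 1e-12))
    stats::pchisq(stat, df = 1, lower.tail = FALSE) < 0.001
  }, logical(1))
  expect_lt(mean(reject), 0.01)
})

test_that("LD blocks give the designed r2 extremes", {
  spec <- simulationSpec(2000, 2, maf = 0.3,
                         ldBlocks = list(list(snps = 1:2, rho = 1)),
                         seed = 17)
  g <- simulateGenotypes(spec)
  expect_equal(ldR2(g, 1, 2)$r2, 1)

  # independent SNPs: squared sample correlation is O(1/n)
  r2s <- vapply(1:30, function(s) {
    g <- simulateGenotypes(simulationSpec(500, 2, maf = 0.3, seed = 1000 + s))
    ldR2(g, 1, 2)$r2
  }, numeric(1))
  expect_lt(mean(r2s), 3 / 500)
})

test_that("phenotype generator matches its closed-form codings", {
  g <- simulateGenotypes(simulationSpec(600, 2, maf = 0.5, seed = 21))
  snp <- snpInfo(g)$snp_id

  # pure noise: mean ~ mu, var ~ sigma^2
  y0 <- simulatePhenotype(g, effectModel(mu = 7, sigma = 1), seed = 2)$trait
  expect_equal(mean(y0), 7, tolerance = 0.2)
  expect_equal(stats::var(y0), 1, tolerance = 0.25)

  # single SNP a = 2, sigma = 0: genotype means mu - 2, mu, mu + 2
  m <- effectModel(mu = 10, additive = stats::setNames(2, snp[1]), sigma = 0)
  y <- simulatePhenotype(g, m, seed = 2)$trait
  cl <- genotypeCalls(g)[, 1]
  expect_equal(as.numeric(tapply(y, cl, mean)), c(8, 10, 12),
               tolerance = 1e-12)

  # pure AxA with coefficient c: cell means mu + c * x1 * x2 exactly
  m <- effectModel(mu = 10, epistasis = data.frame(
    snp1 = snp[1], snp2 = snp[2], type = "AxA", coef = 1.5), sigma = 0)
  y <- simulatePhenotype(g, m, seed = 2)$trait
  x1 <- genotypeCalls(g)[, 1] - 1
  x2 <- genotypeCalls(g)[, 2] - 1
  expect_equal(y, unname(10 + 1.5 * x1 * x2), tolerance = 1e-12)
})

test_that("fitting sigma->0 data recovers the generative a and d exactly", {
  g <- simulateGenotypes(simulationSpec(435, 1, maf = 0.4, seed = 31))
  snp <- snpInfo(g)$snp_id[1]
  m <- effectModel(mu = 40, additive = stats::setNames(0.95, snp),
                   dominance = stats::setNames(-0.4, snp), sigma = 0)
  y <- simulatePhenotype(g, m, seed = 3)$trait
  fit <- additiveDominanceTest(y, genotypeCalls(g)[, 1])
  expect_equal(fit$a_hat, 0.95, tolerance = 1e-8)
  expect_equal(fit$d_hat, -0.4, tolerance = 1e-8)
})

test_that("expression profiles realize planted hub correlations", {
  e <- simulateExpression(c("g1", "g2"), "hub", c(g1 = 1, g2 = -1), seed = 5)
  expect_equal(stats::cor(e["g1", ], e["hub", ]), 1, tolerance = 1e-12)
  expect_equal(stats::cor(e["g2", ], e["hub", ]), -1, tolerance = 1e-12)
  expect_true(all(e > 0))

  e <- simulateExpression("g1", "hub", c(g1 = 0.8), nConditions = 2000,
                          seed = 6)
  expect_equal(stats::cor(e["g1", ], e["hub", ]), 0.8, tolerance = 0.03)
  expect_error(simulateExpression("g1", "hub", c(g1 = 1.2)), "<= 1")
})

test_that("planted promoters scan back to exactly the planted sites", {
  plan <- list(gA = data.frame(motif = "TCACGTGA", offset = 400L),
               gB = data.frame(motif = c("TCACGTGA", "TAAT"),
                               offset = c(700L, 120L)))
  prom <- plantPromoters(plan, geneIds = c("gA", "gB", "gC"), seed = 8)
  hits <- scanMotifs(prom)
  expect_equal(hits$upstream_start[hits$gene_id == "gA"], 400L)
  expect_setequal(hits$upstream_start[hits$gene_id == "gB"], c(700L, 120L))
  expect_equal(sum(hits$gene_id == "gC"), 0L)

  # empty plan: rejection guarantees a motif-free background
  clean <- plantPromoters(list(), geneIds = "gX", length = 1500, seed = 9)
  expect_equal(nrow(scanMotifs(clean)), 0L)

  bad <- list(gA = data.frame(motif = c("TCACGTGA", "TCACGTGA"),
                              offset = c(400L, 403L)))
  expect_error(plantPromoters(bad), "overlap")
})
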