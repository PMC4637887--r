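test_that("genotypic and additive/dominance tests match the lm oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 80
    g <- random_panel(n, maf = 0.35)
    Q <- cbind(q1 = stats::runif(n), q2 = stats::rnorm(n))
    y <- 2 + 0.4 * (g - 1) + Q %*% c(1, -0.5) + stats::rnorm(n)
    y <- as.numeric(y)
    mine <- genotypicTest(y, g, Q)
    ad <- additiveDominanceTest(y, g, Q)
    orc <- oracle_single(y, g, Q)
    expect_equal(mine$m_p, orc$m_p, tolerance = 1e-10)
    expect_equal(mine$r2_explained, orc$r2, tolerance = 1e-10)
    expect_equal(ad$a_hat, orc$a_hat, tolerance = 1e-10)
    expect_equal(ad$a_p, orc$a_p, tolerance = 1e-10)
    expect_equal(ad$d_hat, orc$d_hat, tolerance = 1e-10)
    expect_equal(ad$d_p, orc$d_p, tolerance = 1e-10)
  }
})

test_that("without covariates the genotypic F test is one-way ANOVA", {
  set.seed(3)
  g <- rep(c(0, 1, 2), each = 20)
  y <- stats::rnorm(60) + 0.3 * g
  mine <- genotypicTest(y, g)
  aovP <- summary(stats::aov(y ~ factor(g)))[[1]][1, "Pr(>F)"]
  expect_equal(mine$m_p, aovP, tolerance = 1e-12)
})

test_that("a and d follow their closed forms in the class means", {
  # class means 8, 11, 10 -> a = 1, d = 2
  g <- rep(c(0, 1, 2), each = 5)
  y <- rep(c(8, 11, 10), each = 5)
  fit <- additiveDominanceTest(y, g)
  expect_equal(fit$a_hat, 1, tolerance = 1e-12)
  expect_equal(fit$d_hat, 2, tolerance = 1e-12)

  # flat means: both effects zero
  fit0 <- additiveDominanceTest(rep(10, 15) + rep(c(0, 0, 0), each = 5), g)
  expect_equal(fit0$a_hat, 0, tolerance = 1e-12)
  expect_equal(fit0$d_hat, 0, tolerance = 1e-12)

  # y identical to the genotype code: perfect fit
  gt <- genotypicTest(as.numeric(g), g)
  expect_lt(gt$m_p, 1e-12)
  expect_equal(gt$r2_explained, 1, tolerance = 1e-12)
})

test_that("structure covariates de-confound a structured null SNP", {
  set.seed(71)
  n <- 300
  pop <- rep(0:1, each = n / 2)
  Q <- cbind(q = pop + stats::rnorm(n, 0, 0.05))
  # SNP frequency differs by subpopulation; trait depends on structure only
  maf <- ifelse(pop == 1, 0.45, 0.1)
  reps <- 120
  pAdj <- pRaw <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- stats::rbinom(n, 2, maf)
    y <- 2 * pop + stats::rnorm(n)
    pAdj[i] <- genotypicTest(y, g, Q)$m_p
    pRaw[i] <- genotypicTest(y, g)$m_p
  }
  expect_gt(mean(pRaw < 0.01), 0.3)   # confounding inflates the raw test
  expect_lt(mean(pAdj < 0.01, na.rm = TRUE), 0.08)  # Q adjustment repairs it
})

test_that("significance transform is log10(1/p)", {
  expect_equal(significanceTransform(0.001), 3)
  expect_equal(significanceTransform(1), 0)
  expect_equal(significanceTransform(9.83e-07), log10(1 / 9.83e-07))
  expect_gt(significanceTransform(9.83e-07), 6)
  expect_error(significanceTransform(0), "\\(0, 1\\]")
})

test_that("BH adjustment matches hand-stepped q-values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.037), 0.037)
  expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
  p <- c(0.003, 0.04, 0.02, 0.01, 0.5)
  # hand step-up: sort, p * n / rank, cumulative min from the largest
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(bhAdjust(p)[o], q_sorted)
  # permutation invariance
  perm <- sample(seq_along(p))
  expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  expect_error(bhAdjust(numeric(0)), "empty")
})

test_that("genotype deviations are raw class means about the grand mean", {
  # grand mean 40.14 with het class at 38.55 and minor homozygote at 41.80
  y <- c(rep(40.07, 50), rep(38.55, 50), rep(41.80, 50))
  g <- rep(c(0, 1, 2), each = 50)
  dev <- genotypeDeviations(y, g, alleles = c("A", "G"))
  expect_equal(dev$genotype, c("AA", "AG", "GG"))
  expect_equal(dev$deviation[dev$genotype == "AG"], -1.59, tolerance = 1e-9)
  expect_equal(dev$deviation[dev$genotype == "GG"], 1.66, tolerance = 1e-9)
  expect_equal(sum(dev$n * dev$deviation), 0, tolerance = 1e-9)

  one <- genotypeDeviations(rep(5, 4), rep(1, 4))
  expect_equal(one$deviation, 0)
  bal <- genotypeDeviations(c(1, 1, 3, 3), c(0, 0, 2, 2))
  expect_equal(bal$deviation, c(-1, 1))
})

test_that("the single-locus scan flags a planted effect and skips sanely", {
  g <- simulateGenotypes(simulationSpec(435, 50, maf = 0.3, seed = 202))
  snp <- snpInfo(g)$snp_id
  m <- effectModel(mu = 0, additive = stats::setNames(1, snp[7]), sigma = 1)
  ph <- simulatePhenotype(g, m, seed = 5, traitName = "tr")
  res <- scanSingleLocus(g, ph)
  expect_true(res$significant_a[res$snp_id == snp[7]])
  expect_lt(sum(res$significant_a), 5)  # few false positives alongside

  # monomorphic SNP: skipped with a reason, never silently dropped
  cl <- genotypeCalls(g)
  cl[, 2] <- 0
  g2 <- genotypeMatrix(cl, within(snpInfo(g), {
    maf[2] <- 0
    monomorphic[2] <- TRUE
  }))
  res2 <- scanSingleLocus(g2, ph)
  expect_equal(res2$reason[res2$snp_id == snp[2]], "monomorphic")
  expect_equal(nrow(res2), 50L)
})

test_that("q-values never fall below their p-values within a family", {
  g <- simulateGenotypes(simulationSpec(120, 30, maf = 0.3, seed = 9))
  ph <- simulatePhenotype(g, effectModel(mu = 0, sigma = 1), seed = 10)
  res <- scanSingleLocus(g, ph)
  for (fam in c("m", "a", "d")) {
    p <- res[[paste0(fam, "_p")]]
    q <- res[[paste0(fam, "_q")]]
    ok <- !is.na(p) & !is.na(q)
    expect_true(all(q[ok] >= p[ok] - 1e-12))
  }
})
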