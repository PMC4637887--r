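# Independent brute-force oracles: every statistical result of the package
# is cross-checked against stock lm()/anova() fits or hand enumeration.

# single-locus oracle: 2-df genotype F test, additive/dominance t tests
oracle_single <- function(y, g, Q = NULL) {
  dat <- data.frame(y = y, gf = factor(g), x = g - 1,
                    z = ifelse(g == 1, 0.5, -0.5))
  qn <- character(0)
  if (!is.null(Q)) {
    Qd <- as.data.frame(Q)
    qn <- paste0(".q", seq_along(Qd))
    names(Qd) <- qn
    dat <- cbind(dat, Qd)
  }
  rhs <- function(...) paste(c(qn, ...), collapse = " + ")
  red <- stats::lm(stats::as.formula(paste("y ~", rhs("1"))), dat)
  fullG <- stats::lm(stats::as.formula(paste("y ~", rhs("gf"))), dat)
  m_p <- stats::anova(red, fullG)[2, "Pr(>F)"]
  ad <- stats::lm(stats::as.formula(paste("y ~", rhs("x", "z"))), dat)
  co <- summary(ad)$coefficients
  list(m_p = m_p,
       a_hat = co["x", "Estimate"], a_p = co["x", "Pr(>|t|)"],
       d_hat = co["z", "Estimate"], d_p = co["z", "Pr(>|t|)"],
       r2 = (sum(stats::resid(red)^2) - sum(stats::resid(fullG)^2)) /
         sum((y - mean(y))^2))
}

# epistasis oracle: full vs single-term-dropped lm comparisons
oracle_epistasis <- function(y, g1, g2, Q = NULL) {
  dat <- data.frame(y = y, x1 = g1 - 1, z1 = ifelse(g1 == 1, 0.5, -0.5),
                    x2 = g2 - 1, z2 = ifelse(g2 == 1, 0.5, -0.5))
  dat$axa <- dat$x1 * dat$x2
  dat$axd <- dat$x1 * dat$z2
  dat$dxa <- dat$z1 * dat$x2
  dat$dxd <- dat$z1 * dat$z2
  qn <- character(0)
  if (!is.null(Q)) {
    Qd <- as.data.frame(Q)
    qn <- paste0(".q", seq_along(Qd))
    names(Qd) <- qn
    dat <- cbind(dat, Qd)
  }
  terms <- c("x1", "z1", "x2", "z2", "axa", "axd", "dxa", "dxd")
  fml <- function(use, drop = NULL)
    stats::as.formula(paste("y ~", paste(c(qn, setdiff(use, drop)),
                                         collapse = " + ")))
  # empty two-locus cells alias columns: restrict to the estimable design
  # (lm reports aliased coefficients as NA), as the package does
  allFit <- stats::lm(fml(terms), dat)
  estimable <- terms[!is.na(stats::coef(allFit)[terms])]
  full <- stats::lm(fml(estimable), dat)
  pOf <- function(term) {
    if (!term %in% estimable) return(NA_real_)
    stats::anova(stats::lm(fml(estimable, term), dat), full)[2, "Pr(>F)"]
  }
  intTerms <- intersect(c("axa", "axd", "dxa", "dxd"), estimable)
  list(AxA = pOf("axa"), AxD = pOf("axd"), DxA = pOf("dxa"),
       DxD = pOf("dxd"),
       joint = if (length(intTerms))
         stats::anova(stats::lm(fml(estimable, intTerms), dat),
                      full)[2, "Pr(>F)"] else NA_real_)
}

# hand-coded breadth-first distances from a hub over an undirected edge list
oracle_bfs <- function(edges, hub) {
  adj <- list()
  addE <- function(a, b) {
    adj[[a]] <<- unique(c(adj[[a]], b))
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    addE(a, b); addE(b, a)
  }
  dist <- c(stats::setNames(0, hub))
  queue <- hub
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# per-individual enumeration oracle for allele/genotype combination effects
oracle_combo_axa <- function(y, g1, g2, alleles1, alleles2) {
  rows <- list()
  for (i in seq_along(y)) {
    al1 <- c(rep(alleles1[1], 2 - g1[i]), rep(alleles1[2], g1[i]))
    al2 <- c(rep(alleles2[1], 2 - g2[i]), rep(alleles2[2], g2[i]))
    for (u in al1) for (v in al2)
      rows[[length(rows) + 1L]] <- data.frame(combo = paste0(u, "-", v),
                                              y = y[i], w = 0.25)
  }
  d <- do.call(rbind, rows)
  grand <- mean(y)
  out <- do.call(rbind, lapply(split(d, d$combo), function(s)
    data.frame(combo = s$combo[1],
               effect = sum(s$w * s$y) / sum(s$w) - grand,
               frequency = sum(s$w) / length(y))))
  rownames(out) <- NULL
  out
}

# small random genotype panel with all three classes guaranteed
random_panel <- function(n, maf = 0.3) {
  repeat {
    g <- stats::rbinom(n, 2, maf)
    if (length(unique(g)) == 3L && min(table(g)) >= 3) return(g)
  }
}
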