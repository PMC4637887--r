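# Internal least-squares machinery shared by the association modules.
# Deliberately not lm(): tests cross-check these fits against lm()/anova()
# as an independent oracle.

# QR least squares; aliased columns get NA coefficients.
.ols <- function(X, y) {
  qr_ <- qr(X)
  coef <- qr.coef(qr_, y)
  res <- y - qr.fitted(qr_, y)
  sse <- sum(res * res)
  df_res <- length(y) - qr_$rank
  list(qr = qr_, coef = coef, sse = sse, rank = qr_$rank,
       df_res = df_res, resid = res)
}

# standard errors for estimable coefficients (NA where aliased)
.olsSe <- function(fit) {
  r <- fit$rank
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  piv <- fit$qr$pivot[seq_len(r)]
  xtx_inv <- chol2inv(R)
  sigma2 <- fit$sse / fit$df_res
  se <- rep(NA_real_, length(fit$coef))
  se[piv] <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  se
}

# F-test of a full model against a reduced design (extra-SS test)
.fTest <- function(fullFit, Xred, y) {
  redFit <- .ols(Xred, y)
  dfNum <- fullFit$rank - redFit$rank
  if (dfNum <= 0 || fullFit$df_res <= 0)
    return(list(F = NA_real_, p = NA_real_, df1 = dfNum,
                df2 = fullFit$df_res, sseRed = redFit$sse))
  Fstat <- ((redFit$sse - fullFit$sse) / dfNum) /
    (fullFit$sse / fullFit$df_res)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, dfNum, fullFit$df_res,
                                lower.tail = FALSE),
       df1 = dfNum, df2 = fullFit$df_res, sseRed = redFit$sse)
}

# two-sided t-test p for one coefficient of an .ols fit
.tTest <- function(fit, se, j) {
  if (is.na(fit$coef[j]) || is.na(se[j]) || se[j] == 0 || fit$df_res <= 0)
    return(NA_real_)
  unname(2 * stats::pt(abs(fit$coef[j] / se[j]), fit$df_res,
                       lower.tail = FALSE))
}

# single-locus genetic codings: x additive in {-1,0,+1} per minor-allele
# count, z dominance {-0.5,+0.5,-0.5}; a = half homozygote difference,
# d = heterozygote deviation from the homozygote midpoint.
.geneticCodes <- function(g) {
  list(x = g - 1, z = ifelse(g == 1, 0.5, -0.5))
}

.asCovariateMatrix <- function(Q, ids = NULL) {
  if (is.null(Q)) return(NULL)
  if (is(Q, "data.frame")) {
    if (!is.null(Q[["individual_id"]])) {
      rn <- Q$individual_id
      Q <- as.matrix(Q[, setdiff(names(Q), "individual_id"), drop = FALSE])
      rownames(Q) <- rn
    } else Q <- as.matrix(Q)
  }
  if (!is.null(ids)) {
    if (is.null(rownames(Q)))
      stop("covariates need rownames or an individual_id column ",
           "to align with genotypes")
    Q <- Q[ids, , drop = FALSE]
  }
  Q
}

# deterministic per-stage seed derivation (kept below 2^31)
.substreamSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

.writeTsvFile <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
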