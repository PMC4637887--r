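#' Default pipeline configuration (bundled demo simulation)
#'
#' Returns the configuration the pipeline runs with out of the box: a
#' simulated study with a hub TF gene, ten true target genes and three
#' decoy genes, two quantitative traits driven by additive, dominance and
#' pairwise-epistatic effects plus population-structure effects, planted
#' promoter motifs and four-tissue expression profiles. All thresholds
#' are the analysis defaults (MAF > 0.10; |r| > 0.8; DE screen FC >= 2 or
#' <= 0.5, q <= 0.10, p <= 1e-3; association p <= 0.01, FDR < 0.1).
#'
#' @param seed root seed; every stage derives a named substream from it.
#' @param outDir output directory for \code{\link{runPipeline}}.
#' @return nested configuration list.
#' @export
defaultConfig <- function(seed = 1L, outDir = tempfile("epiGRN_run_")) {
  targets <- sprintf("T%02d", 1:10)
  decoys <- sprintf("D%02d", 1:3)
  genes <- c("HUB", targets, decoys)
  snpsPerGene <- c(6L, rep(5L, length(targets)), rep(4L, length(decoys)))
  corr <- stats::setNames(rep(c(0.95, -0.95, 0.9, -0.9, 0.98), 2), targets)
  offsets <- stats::setNames(rep(c(350L, 500L, 700L, 900L, 420L), 2), targets)
  plan <- lapply(targets, function(g)
    data.frame(motif = "TCACGTGA", offset = offsets[[g]]))
  names(plan) <- targets
  list(
    seed = as.integer(seed),
    outDir = outDir,
    hubGene = "HUB",
    motifs = c("TCACGTGA", "TAAT"),
    windows = list(c(300, 600), c(650, 950)),
    pairSource = "all-within-selected",
    thresholds = list(mafMin = 0.10, rThreshold = 0.8, alpha = 0.01,
                      fdr = 0.1, fcUp = 2, fcDown = 0.5, deP = 1e-3,
                      deQ = 0.10, minClassN = 3L, minMarginal = 3L,
                      minCells = 5L),
    simulation = list(
      nIndividuals = 435L,
      genes = genes,
      snpsPerGene = snpsPerGene,
      mafRange = c(0.15, 0.5),
      causalMaf = 0.4,
      targetCorrelations = corr,
      promoterPlan = plan,
      promoterLength = 2000L,
      gc = 0.4,
      nStructure = 2L,
      structureEffects = c(0.5, -0.5),
      traits = list(
        growth = list(mu = 10, sigma = 1,
                      additive = c("T01-SNP1" = 0.8, "T02-SNP1" = 0.6,
                                   "HUB-SNP1" = 0.5),
                      dominance = c("T03-SNP1" = 0.5),
                      epistasis = data.frame(
                        snp1 = c("HUB-SNP1", "HUB-SNP2", "HUB-SNP1",
                                 "T01-SNP2"),
                        snp2 = c("T01-SNP1", "T02-SNP1", "T03-SNP1",
                                 "T04-SNP1"),
                        type = c("AxA", "AxA", "AxA", "AxA"),
                        coef = c(1.2, 1.2, 1.0, 1.2))),
        wood = list(mu = 40, sigma = 1,
                    additive = c("T05-SNP1" = 0.7, "HUB-SNP3" = 0.5),
                    dominance = c("T06-SNP1" = 0.6),
                    epistasis = data.frame(
                      snp1 = c("HUB-SNP3", "T05-SNP2"),
                      snp2 = c("T05-SNP1", "T06-SNP1"),
                      type = c("AxA", "AxA"),
                      coef = c(1.2, 1.2))))))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultConfig}} (shallow-merged per top-level field;
#' thresholds merged per entry).
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig(seed = user$seed %||% 1L)
  for (nm in setdiff(names(user), "thresholds")) cfg[[nm]] <- user[[nm]]
  for (nm in names(user$thresholds))
    cfg$thresholds[[nm]] <- user$thresholds[[nm]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Range and consistency checks; returns a report instead of failing, so
#' callers can display all problems at once. \code{runPipeline} refuses
#' to start when the report contains errors.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return data.frame(level, field, message); level is "error",
#'   "warning" or "note".
#' @export
validateConfig <- function(config) {
  rows <- list()
  add <- function(level, field, message)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, field = field,
                                             message = message,
                                             stringsAsFactors = FALSE)
  th <- config$thresholds
  inUnit <- function(v) is.numeric(v) && length(v) == 1L && v > 0 && v <= 1
  if (!inUnit(th$alpha)) add("error", "alpha", "alpha must be in (0, 1]")
  if (!inUnit(th$fdr)) add("error", "fdr", "fdr must be in (0, 1]")
  if (!is.null(th$fdr) && inUnit(th$fdr) && th$fdr <= 0.01)
    add("note", "fdr", "strict FDR preset (<= 0.01)")
  if (!is.numeric(th$mafMin) || th$mafMin < 0 || th$mafMin >= 0.5)
    add("error", "mafMin", "mafMin must be in [0, 0.5)")
  if (!is.numeric(th$rThreshold) || th$rThreshold < 0 || th$rThreshold > 1)
    add("error", "rThreshold", "rThreshold must be in [0, 1]")
  if (!is.null(th$fcUp) && !is.null(th$fcDown) &&
      (th$fcUp <= 1 || th$fcDown >= 1))
    add("error", "fc", "need fcUp > 1 and fcDown < 1")
  if (is.null(config$hubGene) || !nzchar(config$hubGene))
    add("error", "hubGene", "hub gene must be set")
  hasSim <- !is.null(config$simulation)
  hasInputs <- !is.null(config$inputs)
  if (hasSim == hasInputs)
    add("error", "inputs",
        "exactly one of 'simulation' or 'inputs' must be provided")
  if (!is.null(config$motifs) && any(!grepl("^[ACGT]+$", config$motifs)))
    add("error", "motifs", "motifs must be over A/C/G/T")
  defaults <- defaultConfig()$thresholds
  for (nm in intersect(names(th), names(defaults))) {
    if (!identical(as.numeric(th[[nm]]), as.numeric(defaults[[nm]])))
      add("note", nm, paste0("non-default threshold (", th[[nm]],
                             ", default ", defaults[[nm]], ")"))
  }
  if (!length(rows))
    return(data.frame(level = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# -- pipeline stages ---------------------------------------------------

.simulateStudy <- function(config) {
  sim <- config$simulation
  genes <- rep(sim$genes, times = sim$snpsPerGene)
  set.seed(.substreamSeed(config$seed, 1L))
  maf <- if (!is.null(sim$mafRange))
    stats::runif(length(genes), sim$mafRange[1], sim$mafRange[2])
  else rep_len(sim$maf %||% 0.3, length(genes))
  # SNPs carrying planted effects sit at an informative frequency: the
  # information for pairwise interaction contrasts lives in the rare
  # double-homozygote cells and vanishes at low MAF
  ids <- paste0(genes, "-SNP", stats::ave(seq_along(genes), genes,
                                          FUN = seq_along))
  causal <- unique(unlist(lapply(sim$traits, function(ts)
    c(names(ts$additive), names(ts$dominance),
      ts$epistasis$snp1, ts$epistasis$snp2))))
  maf[ids %in% causal] <- sim$causalMaf %||% 0.4
  spec <- simulationSpec(
    nIndividuals = sim$nIndividuals, nSnps = length(genes),
    maf = maf,
    geneAssignment = genes,
    seed = .substreamSeed(config$seed, 5L))
  geno <- simulateGenotypes(spec)
  set.seed(.substreamSeed(config$seed, 2L))
  Q <- matrix(stats::runif(sim$nStructure * nIndividuals(geno)),
              ncol = sim$nStructure,
              dimnames = list(individualIds(geno),
                              paste0("Q", seq_len(sim$nStructure))))
  pheno <- NULL
  tix <- 0L
  for (tr in names(sim$traits)) {
    tix <- tix + 1L
    ts <- sim$traits[[tr]]
    model <- effectModel(mu = ts$mu,
                         additive = ts$additive %||% numeric(0),
                         dominance = ts$dominance %||% numeric(0),
                         epistasis = ts$epistasis,
                         structureEffects = sim$structureEffects %||%
                           numeric(0),
                         sigma = ts$sigma)
    ph <- simulatePhenotype(geno, model, Q,
                            seed = .substreamSeed(config$seed, 10L + tix),
                            traitName = tr)
    pheno <- if (is.null(pheno)) ph else cbind(pheno, ph)
  }
  expr <- simulateExpression(sim$genes, config$hubGene,
                             sim$targetCorrelations %||% numeric(0),
                             nConditions = 4L,
                             seed = .substreamSeed(config$seed, 3L))
  prom <- plantPromoters(sim$promoterPlan %||% list(),
                         geneIds = setdiff(sim$genes, config$hubGene),
                         length = sim$promoterLength %||% 2000L,
                         gc = sim$gc %||% 0.4,
                         seed = .substreamSeed(config$seed, 4L))
  list(genotypes = geno, phenotypes = pheno, covariates = Q,
       expression = expr, promoters = prom)
}

.loadStudy <- function(config) {
  inp <- config$inputs
  list(genotypes = readVcf(inp$vcf),
       phenotypes = readPhenotypeTable(inp$phenotypes),
       covariates = if (is.null(inp$covariates)) NULL
                    else readCovariates(inp$covariates),
       expression = readExpressionMatrix(inp$expression),
       promoters = readPromoters(inp$promoters))
}

#' Run the full pipeline from a configuration
#'
#' Stages: data (simulate or load), discover-targets, assoc-single,
#' assoc-epistasis, network. Every result table is written as TSV under
#' \code{config$outDir} together with a run manifest (config hash, seed,
#' per-stage row counts, package version). Identical config and seed
#' reproduce byte-identical outputs. A stage failure aborts with the
#' stage name; files written by the failing stage are kept with a
#' \code{.partial} suffix.
#'
#' @param config configuration list (see \code{\link{defaultConfig}},
#'   \code{\link{readPipelineConfig}}).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  report <- validateConfig(config)
  if (any(report$level == "error"))
    stop("invalid configuration:\n",
         paste(" -", report$field[report$level == "error"],
               report$message[report$level == "error"], collapse = "\n"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  th <- config$thresholds
  manifest <- list(package = "epiGRN",
                   version = as.character(utils::packageVersion("epiGRN")),
                   seed = config$seed, stages = list())
  cfgRecord <- config
  cfgRecord$outDir <- NULL  # so identical runs hash identically anywhere
  jsonlite::write_json(cfgRecord, out("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(out("config.json")))

  stageFiles <- character(0)
  runStage <- function(name, fn) {
    stageFiles <<- character(0)
    res <- tryCatch(fn(), error = function(e) {
      for (f in stageFiles) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  emit <- function(df, f) {
    p <- out(f)
    stageFiles <<- c(stageFiles, p)
    .writeTsvFile(df, p)
  }

  # stage 1: data
  study <- runStage("data", function() {
    st <- if (!is.null(config$simulation)) .simulateStudy(config)
          else .loadStudy(config)
    if (!is.null(config$simulation)) {
      writeVcf(st$genotypes, out("genotypes.vcf"),
               source = paste0("epiGRN simulate seed=", config$seed))
      writeIdTable(st$phenotypes, out("phenotypes.tsv"), "individual_id")
      writeIdTable(st$covariates, out("covariates.tsv"), "individual_id")
      writeIdTable(st$expression, out("expression.tsv"), "gene_id")
      writePromoters(st$promoters, out("promoters.fasta"))
    }
    st
  })
  manifest$stages$data <- list(
    n_individuals = nIndividuals(study$genotypes),
    n_snps = nSnps(study$genotypes))

  # stage 2: target discovery
  targets <- runStage("discover-targets", function() {
    hits <- scanMotifs(study$promoters, config$motifs)
    corr <- expressionCorrelation(study$expression, config$hubGene)
    calls <- selectTargets(hits, corr, th$rThreshold)
    fr <- motifWindowFractions(hits, config$windows)
    emit(hits, "motif_hits.tsv")
    emit(calls, "target_calls.tsv")
    emit(data.frame(window = names(fr), fraction = unname(fr)),
         "motif_window_fractions.tsv")
    list(hits = hits, calls = calls, fractions = fr,
         selected = calls$gene_id[calls$selected])
  })
  manifest$stages$discover_targets <- list(
    n_motif_hits = nrow(targets$hits),
    n_selected = length(targets$selected))

  # stage 3: single-locus association on common SNPs
  common <- filterCommon(study$genotypes, th$mafMin)
  single <- runStage("assoc-single", function() {
    res <- scanSingleLocus(common, study$phenotypes, study$covariates,
                           alpha = th$alpha, fdrMax = th$fdr,
                           minClassN = th$minClassN)
    emit(res, "single_locus.tsv")
    res
  })
  manifest$stages$assoc_single <- list(
    n_tests = nrow(single),
    n_significant = sum(single$significant_a | single$significant_d,
                        na.rm = TRUE))

  # stage 4: epistasis on hub + selected target genes
  epi <- runStage("assoc-epistasis", function() {
    sd_ <- snpInfo(common)
    keepGenes <- c(config$hubGene, targets$selected)
    snps <- sd_$snp_id[sd_$gene_id %in% keepGenes]
    sub <- subsetGenotypes(common, snps = snps)
    pairs <- if (identical(config$pairSource, "hub-vs-targets"))
      hubTargetPairs(sub, config$hubGene)
    else {
      ids <- snpInfo(sub)$snp_id
      cmb <- utils::combn(ids, 2)
      cbind(snp_id1 = cmb[1, ], snp_id2 = cmb[2, ])
    }
    res <- scanEpistasis(sub, study$phenotypes, pairs, study$covariates,
                         alpha = th$alpha, fdrMax = th$fdr,
                         minMarginal = th$minMarginal,
                         minCells = th$minCells)
    emit(res, "epistasis.tsv")
    res
  })
  manifest$stages$assoc_epistasis <- list(
    n_pair_tests = nrow(epi) / 4L,
    n_significant = sum(epi$significant, na.rm = TRUE))

  # stage 5: network
  net <- runStage("network", function() {
    sig <- epi[epi$significant & !is.na(epi$significant), , drop = FALSE]
    edges <- collapseToGeneEdges(sig)
    network <- buildLayers(edges, config$hubGene)
    conn <- connectivityFraction(network, targets$selected)
    emit(data.frame(gene = names(layerOf(network)),
                    layer = as.integer(layerOf(network))), "layers.tsv")
    p <- out("network.sif"); stageFiles <<- c(stageFiles, p)
    exportNetwork(network, p, "SIF")
    p <- out("network.graphml"); stageFiles <<- c(stageFiles, p)
    exportNetwork(network, p, "GraphML")
    emit(networkEdges(network), "network_edges.tsv")
    list(network = network, connectivity = conn)
  })
  manifest$stages$network <- list(
    n_genes = length(layerOf(net$network)),
    n_edges = nrow(networkEdges(net$network)),
    fraction_connected = net$connectivity$fraction_connected)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
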