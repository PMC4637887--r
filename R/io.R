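#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a
#' \linkS4class{GenotypeMatrix}. Genotype codes count the minor allele,
#' determined per site from the loaded cohort: when the ALT allele is the
#' rarer one the code is the ALT count, otherwise the coding flips and the
#' REF allele is counted (recorded in \code{snpInfo()$counted}). Ties at
#' frequency 0.5 count the ALT allele. Missing genotypes (\code{./.})
#' become \code{NA}.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param strict if TRUE a multiallelic or non-SNP record is an error;
#'   if FALSE (default) such records are skipped with a warning.
#' @param geneFromId when TRUE (default) and the ID column looks like
#'   "<gene>-SNP<k>", the gene_id annotation is taken from the ID prefix;
#'   otherwise gene_id is NA unless given in an INFO GENE= field.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readVcf <- function(path, strict = FALSE, geneFromId = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no variant records in ", path)
  snp_ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  if (any(!snp_ok)) {
    if (strict)
      stop("multiallelic or non-SNP record at ",
           paste(fix$CHROM[!snp_ok], fix$POS[!snp_ok],
                 sep = ":", collapse = ", "))
    warning(sum(!snp_ok), " multiallelic/non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp_ok, , drop = FALSE]
  fix <- fix[snp_ok, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic SNP records left in ", path)

  altCount <- function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (length(a) != 2L || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  calls <- t(apply(gt, 1, function(r) vapply(r, altCount, numeric(1))))
  if (ncol(gt) == 1L) calls <- matrix(calls, ncol = 1L,
                                      dimnames = list(rownames(gt), NULL))
  calls <- t(calls)  # individuals x SNPs

  # orient per site to the minor allele
  altFreq <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(altFreq) & altFreq > 0.5
  calls[, flip] <- 2 - calls[, flip]

  ids <- fix$ID
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix$CHROM[noId], ":", fix$POS[noId])
  gene <- rep(NA_character_, nrow(fix))
  if (geneFromId) {
    m <- regexpr("^.+(?=-SNP[0-9]+$)", ids, perl = TRUE)
    gene[m > 0] <- regmatches(ids, m)[m > 0]
  }
  infoGene <- sub(".*GENE=([^;]+).*", "\\1", fix$INFO)
  hasInfoGene <- !is.na(fix$INFO) & grepl("GENE=", fix$INFO)
  gene[hasInfoGene] <- infoGene[hasInfoGene]

  snpData <- data.frame(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene_id = gene,
    maf = .mafFromCalls(calls),
    counted = ifelse(flip, "ref", "alt"),
    monomorphic = FALSE, stringsAsFactors = FALSE)
  snpData$monomorphic <- is.na(snpData$maf) | snpData$maf == 0
  genotypeMatrix(calls, snpData)
}

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits one biallelic SNP record per column with unphased GT fields.
#' Codes are translated back to REF/ALT orientation using the
#' \code{counted} column, so \code{readVcf(writeVcf(g))} preserves
#' genotype codes, positions and alleles.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param source optional string recorded in the \code{##source} header
#'   (the simulators record their seed here).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(genotypes, path, source = "epiGRN") {
  sd <- snpInfo(genotypes)
  cl <- genotypeCalls(genotypes)
  inds <- individualIds(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", source),
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene annotation\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", inds), collapse = "\t")), con)
  gtStrings <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(cl))) {
    x <- cl[, j]
    if (identical(sd$counted[j], "ref")) x <- 2 - x
    gt <- ifelse(is.na(x), "./.", gtStrings[x + 1])
    info <- if (is.na(sd$gene_id[j])) "." else paste0("GENE=", sd$gene_id[j])
    writeLines(paste(c(sd$chrom[j], sd$pos[j], sd$snp_id[j], sd$ref[j],
                       sd$alt[j], ".", "PASS", info, "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the gene id.
#' Sequences are uppercased; N is allowed. Positions within a promoter are
#' counted in bp upstream of the TSS: the last base of the sequence is
#' position 1 (immediately 5' of the TSS).
#'
#' @param path FASTA file.
#' @param maxLength promoters longer than this are an error (default 2000).
#' @return A \code{Biostrings::DNAStringSet} named by gene id.
#' @export
readPromoters <- function(path, maxLength = 2000) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(BiocGenerics::width(seqs) > maxLength))
    stop("promoter longer than ", maxLength, " bp")
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write promoters as FASTA
#' @param promoters named DNAStringSet (or named character vector).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePromoters <- function(promoters, path) {
  if (!is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

# shared TSV reader: first column = identifier, header row required
.readIdTable <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop(what, " table needs an id column plus data: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated identifier(s) in ", what, " table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(suppress))
      if (length(bad))
        stop("non-numeric value in ", what, " table at row ", bad[1],
             " (id ", ids[bad[1]], "), column '", names(vals)[j], "'")
      vals[[j]] <- suppress
    }
  }
  rownames(vals) <- ids
  vals
}

#' Read a phenotype table (individuals x traits, TSV)
#'
#' @param path TSV with a header; first column is the individual id,
#'   remaining columns are numeric traits ("NA" or empty = missing).
#' @return data.frame of traits with individual ids as rownames.
#' @export
readPhenotypeTable <- function(path) .readIdTable(path, "phenotype")

#' Read an expression matrix (genes x conditions, TSV)
#'
#' @param path TSV with header; first column gene id, remaining columns are
#'   non-negative expression values per condition/tissue.
#' @return numeric matrix genes x conditions.
#' @export
readExpressionMatrix <- function(path) {
  m <- as.matrix(.readIdTable(path, "expression"))
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  m
}

#' Read population-structure covariates (Q matrix, TSV)
#'
#' @param path TSV with header; first column individual id, remaining
#'   columns numeric structure components. Missing values are an error.
#' @return numeric matrix individuals x components.
#' @export
readCovariates <- function(path) {
  m <- as.matrix(.readIdTable(path, "covariates"))
  if (anyNA(m)) stop("missing values are not allowed in covariates: ", path)
  m
}

#' Restrict genotypes, phenotypes and covariates to a common cohort
#'
#' All inputs are restricted to the sorted intersection of their individual
#' ids; ids missing from any input are reported as dropped. Calling it
#' again on its own output is a no-op.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param phenotypes data.frame with individual ids as rownames.
#' @param covariates optional matrix/data.frame with individual rownames.
#' @return list(genotypes, phenotypes, covariates, ids, dropped).
#' @export
alignCohort <- function(genotypes, phenotypes, covariates = NULL) {
  sets <- list(individualIds(genotypes), rownames(phenotypes))
  if (!is.null(covariates)) sets <- c(sets, list(rownames(covariates)))
  ids <- sort(Reduce(intersect, sets))
  if (!length(ids)) stop("no individuals shared between inputs")
  dropped <- sort(unique(setdiff(unlist(sets), ids)))
  list(genotypes = subsetGenotypes(genotypes, individuals = ids),
       phenotypes = phenotypes[ids, , drop = FALSE],
       covariates = if (is.null(covariates)) NULL
                    else as.matrix(covariates)[ids, , drop = FALSE],
       ids = ids, dropped = dropped)
}

#' Write a phenotype/expression/covariate table as TSV
#'
#' @param x matrix or data.frame with ids as rownames.
#' @param path output file.
#' @param idColumn name of the first (identifier) column.
#' @return \code{path}, invisibly.
#' @export
writeIdTable <- function(x, path, idColumn = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  .writeTsvFile(df, path)
}
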