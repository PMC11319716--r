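#' GenotypeExperiment: genotype matrix plus binary phenotype
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `genotype` assay (SNPs in rows, subjects in columns, entries the minor
#' allele count 0/1/2) and the binary phenotype in `colData(x)$phenotype`.
#' SNP annotation (e.g. `maf`, `role` = `"causal"`/`"null"`) lives in
#' `rowData(x)`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @aliases GenotypeExperiment-class
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- NULL
  if (!"genotype" %in% assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- assay(object, "genotype")
    bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
    if (any(bad))
      msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be unique")
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 subjects are required")
  if ("phenotype" %in% colnames(colData(object))) {
    y <- colData(object)$phenotype
    if (!all(y %in% c(0L, 1L) | is.na(y)))
      msg <- c(msg, "phenotype must be binary 0/1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeExperiment
#'
#' @param genotype integer matrix of minor-allele counts. Orientation is
#'   detected from `subjectsInRows`; internally SNPs are stored in rows.
#' @param phenotype optional binary 0/1 vector, one value per subject.
#' @param snpInfo optional data.frame of per-SNP annotation (e.g. `maf`,
#'   `role`), one row per SNP.
#' @param subjectsInRows logical; `TRUE` when `genotype` comes in the
#'   subjects-by-SNPs orientation used by the TSV interchange format.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' g <- matrix(sample(0:2, 20, TRUE), nrow = 4,
#'             dimnames = list(paste0("s", 1:4), paste0("rs", 1:5)))
#' ge <- GenotypeExperiment(g, phenotype = c(0, 1, 0, 1))
#' @export
GenotypeExperiment <- function(genotype, phenotype = NULL, snpInfo = NULL,
                               subjectsInRows = TRUE) {
  genotype <- as.matrix(genotype)
  if (subjectsInRows) genotype <- t(genotype)
  storage.mode(genotype) <- "integer"
  if (is.null(rownames(genotype)))
    rownames(genotype) <- paste0("snp", seq_len(nrow(genotype)))
  if (is.null(colnames(genotype)))
    colnames(genotype) <- paste0("subj", seq_len(ncol(genotype)))
  cd <- S4Vectors::DataFrame(row.names = colnames(genotype))
  if (!is.null(phenotype)) {
    if (length(phenotype) != ncol(genotype))
      stop("phenotype length must equal the number of subjects")
    cd$phenotype <- as.integer(phenotype)
  }
  rd <- if (is.null(snpInfo)) S4Vectors::DataFrame(row.names = rownames(genotype))
        else S4Vectors::DataFrame(snpInfo, row.names = rownames(genotype))
  se <- SummarizedExperiment(assays = list(genotype = genotype),
                             colData = cd, rowData = rd)
  new("GenotypeExperiment", se)
}

#' Pattern catalog of interaction models
#'
#' Holds the deduplicated catalog of interaction patterns evaluated per SNP
#' pair: one row per pattern class with its model structure, the inheritance
#' mode/direction coding of each SNP, and whether the class is symmetric
#' under swapping the two SNPs (asymmetric classes are fitted in both
#' orientations so that scans do not depend on SNP order).
#'
#' @slot patterns data.frame with columns `pattern_id`, `structure`,
#'   `coding1`, `coding2`, `symmetric`, `k`.
#' @aliases PatternCatalog-class
#' @exportClass PatternCatalog
setClass("PatternCatalog", representation(patterns = "data.frame"))

setValidity("PatternCatalog", function(object) {
  need <- c("pattern_id", "structure", "coding1", "coding2", "symmetric", "k")
  if (!all(need %in% names(object@patterns)))
    return(paste("patterns must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@patterns$pattern_id))
    return("pattern ids must be unique")
  TRUE
})

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "SNPs x", ncol(object),
      "subjects\n")
  if ("phenotype" %in% colnames(colData(object))) {
    y <- colData(object)$phenotype
    cat("  phenotype: ", sum(y == 1L, na.rm = TRUE), " cases / ",
        sum(y == 0L, na.rm = TRUE), " controls\n", sep = "")
  }
  if ("role" %in% colnames(rowData(object))) {
    tb <- table(rowData(object)$role)
    cat("  SNP roles:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "PatternCatalog", function(object) {
  p <- object@patterns
  cat("PatternCatalog with", nrow(p), "interaction patterns\n")
  tb <- table(p$structure)
  cat(" ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
  invisible(object)
})
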