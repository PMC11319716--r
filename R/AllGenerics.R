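#' @rdname GenotypeExperiment
#' @param x a `GenotypeExperiment`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeExperiment
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeExperiment
#' @param value replacement value.
#' @export
setGeneric("phenotype<-", function(x, value) standardGeneric("phenotype<-"))

#' @rdname GenotypeExperiment
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname PatternCatalog
#' @param x a `PatternCatalog`.
#' @export
setGeneric("patternTable", function(x) standardGeneric("patternTable"))

#' Genotype matrix, SNPs in rows
#' @rdname GenotypeExperiment
#' @export
setMethod("genotypes", "GenotypeExperiment", function(x) assay(x, "genotype"))

#' @rdname GenotypeExperiment
#' @export
setMethod("phenotype", "GenotypeExperiment", function(x) {
  if (!"phenotype" %in% colnames(colData(x))) return(NULL)
  setNames(colData(x)$phenotype, colnames(x))
})

#' @rdname GenotypeExperiment
#' @export
setReplaceMethod("phenotype", "GenotypeExperiment", function(x, value) {
  colData(x)$phenotype <- as.integer(value)
  validObject(x)
  x
})

#' @rdname GenotypeExperiment
#' @export
setMethod("snpInfo", "GenotypeExperiment", function(x)
  as.data.frame(rowData(x)))

#' The catalog as a data.frame
#' @rdname PatternCatalog
#' @export
setMethod("patternTable", "PatternCatalog", function(x) x@patterns)
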