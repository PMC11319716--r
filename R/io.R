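## File interchange. Genotype TSV dialect: tab-separated, header row with
## SNP ids, first column the subject id, entries the minor-allele count
## 0/1/2. Phenotype TSV: subject id, 0/1 outcome. VCF import uses the GT
## field of biallelic records and converts to minor-allele counts after
## determining the minor allele from the sample allele frequency.

#' Read a genotype matrix
#'
#' @param path input file.
#' @param format `"tsv"` (subjects x SNPs minor-allele counts) or `"vcf"`
#'   (GT field of biallelic records; needs the `vcfR` package).
#' @param missing `"drop"` removes subjects with any missing genotype;
#'   `"error"` rejects files containing missing genotypes.
#' @return a [GenotypeExperiment-class].
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"),
                          missing = c("drop", "error")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  g <- if (format == "tsv") .readGenotypeTsv(path) else .readGenotypeVcf(path)
  if (anyNA(g)) {
    if (missing == "error") stop("missing genotypes present")
    g <- g[stats::complete.cases(g), , drop = FALSE]
  }
  if (anyDuplicated(colnames(g))) stop("duplicate SNP ids")
  GenotypeExperiment(g)
}

.readGenotypeTsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("malformed genotype TSV: need subject id + SNPs")
  subj <- as.character(d[[1]])
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g)))
    stop("malformed genotype TSV: entries must be 0, 1, 2 or NA")
  rownames(g) <- subj
  g
}

.readGenotypeVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sum(!bi), " non-biallelic record(s) skipped")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no usable GT records in VCF")
  alt <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  ids <- rownames(gt)
  noid <- is.na(ids) | ids == "." | ids == ""
  if (any(noid))
    ids[noid] <- paste0(v@fix[noid, "CHROM"], "_", v@fix[noid, "POS"])
  rownames(alt) <- ids
  ## minor-allele convention: flip records where ALT is the major allele;
  ## a tie at 0.5 keeps ALT as the minor allele
  altFreq <- rowMeans(alt, na.rm = TRUE) / 2
  flip <- !is.na(altFreq) & altFreq > 0.5
  alt[flip, ] <- 2L - alt[flip, , drop = FALSE]
  t(alt)
}

#' Write a genotype matrix as TSV
#'
#' @param x a [GenotypeExperiment-class] or subjects-by-SNPs matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  g <- if (is(x, "GenotypeExperiment")) t(genotypes(x)) else as.matrix(x)
  d <- data.frame(subject_id = rownames(g), g, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a binary phenotype TSV
#'
#' @param path file with columns subject id and 0/1 phenotype.
#' @return named integer vector of 0/1 values.
#' @export
readPhenotype <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("malformed phenotype TSV")
  y <- as.integer(d[[2]])
  if (!all(y %in% c(0L, 1L) | is.na(y))) stop("phenotype must be binary 0/1")
  setNames(y, as.character(d[[1]]))
}

#' @rdname readPhenotype
#' @param y named binary vector.
#' @export
writePhenotype <- function(y, path) {
  d <- data.frame(subject_id = if (is.null(names(y))) seq_along(y)
                               else names(y),
                  phenotype = as.integer(y))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read scan results as TSV
#'
#' Column layout: `snp1, snp2, pattern_id, bic, p_pair, p_main1, p_main2,
#' sig_1p, sig_3p, boot_freq, class` (missing optional columns are written
#' empty). Round-trip stable.
#'
#' @param results a scan results data.frame.
#' @param path output file.
#' @return `path` invisibly (`writeResults`); the data.frame
#'   (`readResults`).
#' @export
writeResults <- function(results, path) {
  cols <- c("snp1", "snp2", "pattern_id", "bic", "p_pair", "p_main1",
            "p_main2", "sig_1p", "sig_3p", "boot_freq", "class")
  for (cn in cols) if (is.null(results[[cn]])) results[[cn]] <- NA
  write.table(results[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
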