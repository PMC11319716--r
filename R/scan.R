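#' Pairwise interaction scan over a genotype dataset
#'
#' Runs [sipiPair()] on every requested SNP pair, computes best-mode main
#' effects once per SNP, and flags each pair under both significance rules.
#' Subjects with a missing genotype in either SNP of a pair are dropped for
#' that pair (complete-case policy; set `missing = "error"` to reject
#' incomplete data instead). Optionally skips pairs in which both main
#' effects are weaker than `prefilterPmain` — the null-null exclusion
#' strategy for variable reduction.
#'
#' @param x a [GenotypeExperiment-class], or a subjects-by-SNPs genotype
#'   matrix with SNP ids as column names.
#' @param y binary outcome; defaults to `phenotype(x)` for a
#'   `GenotypeExperiment`.
#' @param pairs optional 2-column matrix (SNP ids or indices) restricting the
#'   scan; default all `countPairs(m)` pairs.
#' @param catalog a [PatternCatalog-class].
#' @param criterion p-pair criterion; default the pairwise Bonferroni
#'   threshold `alpha / countPairs(m)`.
#' @param alpha family-wise level used for the default criterion.
#' @param prefilterPmain optional main-effect screen threshold: pairs with
#'   both `p_main` values above it are not fitted (reported with NA
#'   `p_pair`, not significant).
#' @param pMethod passed to [sipiPair()].
#' @param withAAFull when `TRUE`, adds the AA-Full comparator p-value column
#'   `p_aa_full`.
#' @param missing `"drop"` (complete-case per pair) or `"error"`.
#' @return data.frame with one row per pair: `snp1`, `snp2`, `pattern_id`,
#'   `structure`, `orientation`, `bic`, `p_pair`, `p_main1`, `p_main2`,
#'   `sig_1p`, `sig_3p`, `evaluable` (and `p_aa_full` on request). The
#'   criterion used is attached as attribute `"criterion"`.
#' @export
scanPairs <- function(x, y = NULL, pairs = NULL, catalog = enumeratePatterns(),
                      criterion = NULL, alpha = 0.05, prefilterPmain = NULL,
                      pMethod = c("wald", "lrt"), withAAFull = FALSE,
                      missing = c("drop", "error")) {
  pMethod <- match.arg(pMethod)
  missing <- match.arg(missing)
  if (is(x, "GenotypeExperiment")) {
    gmat <- genotypes(x)                       # SNPs x subjects
    if (is.null(y)) y <- phenotype(x)
  } else {
    gmat <- t(as.matrix(x))
    if (is.null(rownames(gmat)))
      rownames(gmat) <- paste0("snp", seq_len(nrow(gmat)))
  }
  if (is.null(y)) stop("a phenotype is required")
  y <- as.numeric(y)
  if (length(y) != ncol(gmat)) stop("phenotype length must match subjects")
  if (!all(y %in% c(0, 1) | is.na(y))) stop("phenotype must be binary 0/1")
  if (missing == "error" && (anyNA(gmat) || anyNA(y)))
    stop("missing genotypes or phenotypes present and missing = 'error'")

  m <- nrow(gmat)
  if (m < 2L) stop("at least 2 SNPs are required")
  snp_ids <- rownames(gmat)
  if (is.null(pairs)) {
    pairs <- .allPairs(m)
  } else {
    pairs <- as.matrix(pairs)
    if (!is.numeric(pairs)) {
      pairs <- cbind(match(pairs[, 1], snp_ids), match(pairs[, 2], snp_ids))
      if (anyNA(pairs)) stop("unknown SNP id in pairs")
    }
    storage.mode(pairs) <- "integer"
  }
  if (is.null(criterion)) criterion <- bonferroniThreshold(alpha, countPairs(m))

  ## per-SNP best-mode main effects on complete cases of that SNP
  p_main <- .mainEffects(gmat, y)

  np <- nrow(pairs)
  pm1v <- p_main[pairs[, 1]]
  pm2v <- p_main[pairs[, 2]]
  pattern_id <- rep(NA_character_, np)
  structure_v <- rep(NA_character_, np)
  orientation <- rep(NA_integer_, np)
  bic <- p_pair <- rep(NA_real_, np)
  evaluable <- rep(FALSE, np)
  p_aa <- rep(NA_real_, np)

  anyMissing <- anyNA(gmat) || anyNA(y)
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!is.null(prefilterPmain)) {
      if ((is.na(pm1v[r]) || pm1v[r] > prefilterPmain) &&
          (is.na(pm2v[r]) || pm2v[r] > prefilterPmain)) next
    }
    g1 <- gmat[i, ]; g2 <- gmat[j, ]
    if (anyMissing) {
      ok <- !is.na(g1) & !is.na(g2) & !is.na(y)
      g1 <- g1[ok]; g2 <- g2[ok]; yy <- y[ok]
    } else yy <- y
    if (length(unique(g1)) < 2L || length(unique(g2)) < 2L ||
        length(unique(yy)) < 2L) next
    fit <- sipiPair(g1, g2, yy, catalog = catalog, pMethod = pMethod)
    pattern_id[r] <- fit$pattern_id
    structure_v[r] <- fit$structure
    orientation[r] <- fit$orientation
    bic[r] <- fit$bic
    p_pair[r] <- fit$p_pair
    evaluable[r] <- fit$evaluable
    if (withAAFull)
      p_aa[r] <- aaFull(g1, g2, yy)$p
  }
  res <- data.frame(
    snp1 = snp_ids[pairs[, 1]], snp2 = snp_ids[pairs[, 2]],
    pattern_id = pattern_id, structure = structure_v,
    orientation = orientation, bic = bic, p_pair = p_pair,
    p_main1 = pm1v, p_main2 = pm2v,
    sig_1p = evalRule(p_pair, criterion = criterion, rule = "1pRule"),
    sig_3p = evalRule(p_pair, pm1v, pm2v, criterion = criterion,
                      rule = "3pRule"),
    evaluable = evaluable, stringsAsFactors = FALSE, row.names = NULL)
  if (withAAFull) res$p_aa_full <- p_aa
  attr(res, "criterion") <- criterion
  res
}

#' Label pairs by causal/null class
#'
#' Partitions scanned pairs into `C-C` (a designated causal pair), `C-N`
#' (one causal-pair SNP, one null SNP), `N-N` (two null SNPs) and
#' `C-C-other` (two causal-pair SNPs that do not form a designated pair).
#'
#' @param results a data.frame with `snp1`, `snp2` columns (e.g. from
#'   [scanPairs()]).
#' @param roles named character vector of SNP roles, values `"causal"` or
#'   `"null"`.
#' @param causalPairs 2-column matrix/data.frame of designated causal pair
#'   SNP ids.
#' @return `results` with a `class` column added.
#' @export
classifyPairs <- function(results, roles, causalPairs) {
  causalPairs <- as.matrix(causalPairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ck <- key(causalPairs[, 1], causalPairs[, 2])
  r1 <- roles[results$snp1]; r2 <- roles[results$snp2]
  cls <- ifelse(r1 == "causal" & r2 == "causal", "C-C-other",
         ifelse(r1 == "null" & r2 == "null", "N-N", "C-N"))
  cls[key(results$snp1, results$snp2) %in% ck] <- "C-C"
  results$class <- cls
  results
}
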