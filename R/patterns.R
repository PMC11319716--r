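## The 45-pattern catalog.
##
## Candidate models arise from 4 structures x 6 codings for SNP1 x 6 codings
## for SNP2 (144 in total):
##   full      y ~ c1(g1) + c2(g2) + c1(g1):c2(g2)
##   snp1_int  y ~ c1(g1) + c1(g1):c2(g2)
##   snp2_int  y ~ c2(g2) + c1(g1):c2(g2)
##   int_only  y ~ c1(g1):c2(g2)
## Many candidates are statistically equivalent: two candidates are duplicates
## iff their design matrices span the same column space on the generic 9-row
## genotype table covering all (g1, g2) in {0,1,2}^2, or do so after swapping
## the two SNPs (a pair is unordered). Deduplication under this relation
## leaves exactly 45 pattern classes: 6 full, 18 main-plus-interaction and 21
## interaction-only. Asymmetric classes are fitted in both orientations at
## scan time, which makes results invariant to SNP order.

.pkg_cache <- new.env(parent = emptyenv())

.COD_KEYS <- c("Add", "Dom", "Rec", "AddR", "DomR", "RecR")

## bank layout for one pair: columns 1..6 = codings of g1, 7..12 = codings of
## g2, 12 + (a-1)*6 + b = coding a of g1 times coding b of g2.
.bankMain1 <- function(a) a
.bankMain2 <- function(b) 6L + b
.bankProd <- function(a, b) 12L + (a - 1L) * 6L + b

## design column indices (intercept implicit) for an ordered candidate
.designIdx <- function(structure, a, b) {
  switch(structure,
         full = c(.bankMain1(a), .bankMain2(b), .bankProd(a, b)),
         snp1_int = c(.bankMain1(a), .bankProd(a, b)),
         snp2_int = c(.bankMain2(b), .bankProd(a, b)),
         int_only = .bankProd(a, b))
}

## the 48-column coded-column bank for a concrete pair
.pairColumnBank <- function(g1, g2) {
  n <- length(g1)
  bank <- matrix(0, nrow = n, ncol = 48L)
  for (a in seq_len(6L)) bank[, a] <- .codeByKey(g1, .COD_KEYS[a])
  for (b in seq_len(6L)) bank[, 6L + b] <- .codeByKey(g2, .COD_KEYS[b])
  for (a in seq_len(6L)) for (b in seq_len(6L))
    bank[, .bankProd(a, b)] <- bank[, a] * bank[, 6L + b]
  bank
}

## projection-matrix fingerprint of a design's column space
.spanKey <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  paste(round(Q %*% t(Q), 8), collapse = ",")
}

#' Enumerate the deduplicated catalog of interaction patterns
#'
#' Generates all 144 structure x coding x coding candidates, removes
#' statistically equivalent duplicates (identical design-matrix column space
#' on the generic 9-row genotype table, directly or after swapping the two
#' SNPs) and returns the canonical catalog. The deduplicated catalog always
#' contains exactly 45 patterns; any other count signals a construction
#' defect and raises an error.
#'
#' @return A [PatternCatalog-class] with 45 patterns.
#' @examples
#' cat45 <- enumeratePatterns()
#' nrow(patternTable(cat45))  # 45
#' @export
enumeratePatterns <- function() {
  if (!is.null(.pkg_cache$catalog)) return(.pkg_cache$catalog)

  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  bank <- .pairColumnBank(grid$g1, grid$g2)
  structures <- c("full", "snp1_int", "snp2_int", "int_only")

  cand <- expand.grid(b = seq_len(6L), a = seq_len(6L),
                      structure = structures, stringsAsFactors = FALSE)
  ## canonical order: structure, then coding of SNP1, then coding of SNP2
  cand <- cand[order(match(cand$structure, structures), cand$a, cand$b), ]

  key <- character(nrow(cand))
  keySwap <- character(nrow(cand))
  swapStruct <- c(full = "full", snp1_int = "snp2_int",
                  snp2_int = "snp1_int", int_only = "int_only")
  for (i in seq_len(nrow(cand))) {
    s <- cand$structure[i]; a <- cand$a[i]; b <- cand$b[i]
    key[i] <- .spanKey(cbind(1, bank[, .designIdx(s, a, b), drop = FALSE]))
    ## the same model applied to the swapped pair (g2, g1)
    keySwap[i] <- .spanKey(cbind(1, bank[, .designIdx(swapStruct[[s]], b, a),
                                         drop = FALSE]))
  }
  orbit <- vapply(seq_along(key), function(i)
    paste(sort(c(key[i], keySwap[i])), collapse = "|"), "")

  keep <- !duplicated(orbit)
  reps <- cand[keep, , drop = FALSE]
  sym <- (key == keySwap)[keep]

  short <- c(full = "full", snp1_int = "main", snp2_int = "main",
             int_only = "int")
  structOut <- c(full = "full", snp1_int = "main_int", snp2_int = "main_int",
                 int_only = "int_only")
  kOut <- c(full = 4L, snp1_int = 3L, snp2_int = 3L, int_only = 2L)
  pat <- data.frame(
    pattern_id = paste(short[reps$structure], .COD_KEYS[reps$a],
                       .COD_KEYS[reps$b], sep = "_"),
    structure = unname(structOut[reps$structure]),
    coding1 = .COD_KEYS[reps$a],
    coding2 = .COD_KEYS[reps$b],
    symmetric = sym,
    k = unname(kOut[reps$structure]),
    row.names = NULL, stringsAsFactors = FALSE)

  if (nrow(pat) != 45L)
    stop("catalog construction error: deduplication yielded ", nrow(pat),
         " patterns instead of 45")
  catalog <- new("PatternCatalog", patterns = pat)
  .pkg_cache$catalog <- catalog
  catalog
}

## Ordered-design fitting plan for a catalog: the bank column indices of every
## design the scan fits (1 for symmetric patterns, 2 orientations otherwise),
## plus the pattern row and orientation each design belongs to.
.scanPlan <- function(catalog) {
  if (!is.null(.pkg_cache$plan)) return(.pkg_cache$plan)
  pat <- patternTable(catalog)
  designs <- list()
  pattern <- integer(0)
  orientation <- integer(0)
  for (i in seq_len(nrow(pat))) {
    a <- match(pat$coding1[i], .COD_KEYS)
    b <- match(pat$coding2[i], .COD_KEYS)
    s <- switch(pat$structure[i], full = "full", main_int = "snp1_int",
                int_only = "int_only")
    designs[[length(designs) + 1L]] <- .designIdx(s, a, b)
    pattern <- c(pattern, i)
    orientation <- c(orientation, 1L)
    if (!pat$symmetric[i]) {
      sSwap <- if (s == "snp1_int") "snp2_int" else s
      designs[[length(designs) + 1L]] <- .designIdx(sSwap, b, a)
      pattern <- c(pattern, i)
      orientation <- c(orientation, 2L)
    }
  }
  plan <- list(designs = designs, pattern = pattern, orientation = orientation)
  .pkg_cache$plan <- plan
  plan
}

#' Design matrix of one pattern for a concrete SNP pair
#'
#' Builds the logistic design matrix (including intercept) of a catalog
#' pattern applied to two genotype vectors. `orientation = 2` swaps the roles
#' of the two SNPs (only meaningful for asymmetric patterns).
#'
#' @param pattern_id a pattern id from [enumeratePatterns()].
#' @param g1,g2 genotype vectors with values in `{0, 1, 2}`.
#' @param orientation 1 or 2.
#' @param catalog a [PatternCatalog-class].
#' @return numeric design matrix, the interaction term in the last column.
#' @export
patternDesign <- function(pattern_id, g1, g2, orientation = 1L,
                          catalog = enumeratePatterns()) {
  pat <- patternTable(catalog)
  i <- match(pattern_id, pat$pattern_id)
  if (is.na(i)) stop("unknown pattern id: ", pattern_id)
  a <- match(pat$coding1[i], .COD_KEYS)
  b <- match(pat$coding2[i], .COD_KEYS)
  s <- switch(pat$structure[i], full = "full", main_int = "snp1_int",
              int_only = "int_only")
  if (orientation == 2L) {
    s <- switch(s, snp1_int = "snp2_int", s)
    tmp <- a; a <- b; b <- tmp
  }
  bank <- .pairColumnBank(g1, g2)
  cbind(`(Intercept)` = 1, bank[, .designIdx(s, a, b), drop = FALSE])
}

#' Export the pattern catalog as TSV
#'
#' Writes one row per pattern (id, structure, codings, symmetry, number of
#' coefficients) for audit against other implementations.
#'
#' @param catalog a [PatternCatalog-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  write.table(patternTable(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
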