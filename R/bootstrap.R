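#' Bootstrap resample of a genotype dataset
#'
#' Draws subjects with replacement, keeping genotype rows and phenotype
#' together; the resample has the same subject count as the input.
#'
#' @param x a [GenotypeExperiment-class] or subjects-by-SNPs matrix.
#' @param seed optional integer seed for a reproducible draw.
#' @return an object of the same type as `x`, with subjects resampled (a
#'   `GenotypeExperiment` keeps its phenotype and SNP annotation; resampled
#'   subjects get unique suffixed names).
#' @export
bootData <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is(x, "GenotypeExperiment")) ncol(x) else nrow(x)
  idx <- sample.int(n, n, replace = TRUE)
  if (is(x, "GenotypeExperiment")) {
    out <- x[, idx]
    colnames(out) <- make.unique(colnames(x)[idx])
    out
  } else {
    out <- x[idx, , drop = FALSE]
    rownames(out) <- make.unique(rownames(x)[idx])
    out
  }
}

#' Bootstrap selection frequencies for interaction pairs (boot3p)
#'
#' Reruns the full pattern scan (including per-replicate main effects) on `B`
#' bootstrap resamples, flags pairs per the chosen rule in every replicate,
#' and reports each pair's selection frequency together with the selection
#' indicator at each frequency threshold. Per-replicate seeds are derived
#' deterministically from `seed`, so results do not depend on execution
#' order.
#'
#' @inheritParams scanPairs
#' @param B number of bootstrap replicates.
#' @param thresholds selection-frequency thresholds in (0, 1], ascending.
#' @param rule `"3pRule"` (default) or `"1pRule"` applied inside each
#'   replicate.
#' @param seed integer root seed.
#' @return data.frame with `snp1`, `snp2`, `count`, `freq` and one logical
#'   column `sel_<tau>` per threshold; attributes `B`, `rule`, `thresholds`.
#' @export
boot3p <- function(x, y = NULL, pairs = NULL, catalog = enumeratePatterns(),
                   criterion = NULL, alpha = 0.05, B = 500L,
                   thresholds = c(0.75, 0.80, 0.85, 0.90),
                   rule = c("3pRule", "1pRule"), seed = 1L,
                   prefilterPmain = NULL) {
  rule <- match.arg(rule)
  stopifnot(B >= 1L, all(thresholds > 0), all(thresholds <= 1),
            !is.unsorted(thresholds))
  if (is(x, "GenotypeExperiment") && is.null(y)) y <- phenotype(x)
  gmat <- if (is(x, "GenotypeExperiment")) t(genotypes(x)) else as.matrix(x)
  n <- nrow(gmat)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, B)

  sigCol <- if (rule == "3pRule") "sig_3p" else "sig_1p"
  count <- NULL
  template <- NULL
  for (b in seq_len(B)) {
    set.seed(repSeeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    sc <- scanPairs(gmat[idx, , drop = FALSE], y = y[idx], pairs = pairs,
                    catalog = catalog, criterion = criterion, alpha = alpha,
                    prefilterPmain = prefilterPmain)
    if (is.null(count)) {
      count <- integer(nrow(sc))
      template <- sc[, c("snp1", "snp2")]
    }
    count <- count + as.integer(sc[[sigCol]])
  }
  out <- data.frame(template, count = count, freq = count / B,
                    stringsAsFactors = FALSE)
  for (tau in thresholds)
    out[[sprintf("sel_%g", tau)]] <- out$freq >= tau
  attr(out, "B") <- B
  attr(out, "rule") <- rule
  attr(out, "thresholds") <- thresholds
  out
}
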