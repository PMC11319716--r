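## Per-pair pattern scan: fit every catalog pattern (both orientations where
## the pattern is asymmetric), keep converged non-degenerate fits, select the
## smallest BIC, and report the interaction-term p-value of the winner.

## fast bank: all 48 coded columns are functions of the 9 joint genotype
## cells, so a single row-indexing of the 9 x 48 generic bank builds them.
.gridBank <- function() {
  if (is.null(.pkg_cache$gridBank)) {
    grid <- expand.grid(g1 = 0:2, g2 = 0:2)
    gb <- .pairColumnBank(grid$g1, grid$g2)
    ## row order must match joint index 3*g1 + g2 + 1
    ord <- order(3L * grid$g1 + grid$g2)
    .pkg_cache$gridBank <- gb[ord, , drop = FALSE]
  }
  .pkg_cache$gridBank
}

.bankFor <- function(g1, g2) .gridBank()[3L * g1 + g2 + 1L, , drop = FALSE]

## raw per-design fit table for one pair (one row per ordered design).
## Every design column is constant within the 9 joint-genotype cells, so the
## fits run on the binomial-aggregated 9-row representation (identical
## likelihood) at a cost independent of the subject count.
.fitAllDesigns <- function(g1, g2, y, catalog) {
  plan <- .scanPlan(catalog)
  joint <- 3L * as.integer(g1) + as.integer(g2) + 1L
  ncell <- tabulate(joint, nbins = 9L)
  ycell <- tabulate(joint[y == 1], nbins = 9L)
  f <- .fit_designs_cpp(.gridBank(), as.numeric(ncell), as.numeric(ycell),
                        plan$designs, 50L, 1e-8, 15)
  f$pattern <- plan$pattern
  f$orientation <- plan$orientation
  n <- length(y)
  f$bic <- f$k * log(n) - 2 * f$logLik
  f$p_int <- 2 * pnorm(-abs(f$b_int / f$se_int))
  f
}

#' Scan one SNP pair over the 45-pattern catalog
#'
#' Fits every catalog pattern to the pair (asymmetric patterns in both
#' orientations), restricts the competition to converged, non-separated,
#' non-degenerate fits, selects the pattern with the smallest BIC (ties
#' broken by catalog order) and returns the interaction-term p-value of the
#' selected fit as `p_pair`.
#'
#' @param g1,g2 genotype vectors in `{0, 1, 2}`, both non-constant.
#' @param y binary 0/1 outcome with both classes.
#' @param catalog a [PatternCatalog-class].
#' @param pMethod `"wald"` (default) tests the interaction coefficient of the
#'   selected fit; `"lrt"` compares the selected fit against the same model
#'   without its interaction term by a 1-df likelihood-ratio test.
#' @param details when `TRUE`, the per-design fit table is attached as
#'   attribute `"fits"`.
#' @return list with `pattern_id`, `structure`, `orientation`, `bic`,
#'   `p_pair`, `logLik`, `k`, `n_eligible` and `evaluable` (FALSE when no
#'   pattern produced a usable fit).
#' @examples
#' g1 <- sample(0:2, 400, TRUE, c(.49, .42, .09))
#' g2 <- sample(0:2, 400, TRUE, c(.36, .48, .16))
#' y <- rbinom(400, 1, 0.5)
#' sipiPair(g1, g2, y)$p_pair
#' @export
sipiPair <- function(g1, g2, y, catalog = enumeratePatterns(),
                     pMethod = c("wald", "lrt"), details = FALSE) {
  pMethod <- match.arg(pMethod)
  g1 <- as.integer(g1); g2 <- as.integer(g2)
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("invalid genotype: entries must be 0, 1 or 2")
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("genotype columns must be non-constant")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("outcome must be binary with both classes present")

  f <- .fitAllDesigns(g1, g2, y, catalog)
  eligible <- f$converged & !f$separated & !f$degenerate
  out <- list(pattern_id = NA_character_, structure = NA_character_,
              orientation = NA_integer_, bic = NA_real_, p_pair = NA_real_,
              logLik = NA_real_, k = NA_integer_,
              n_eligible = sum(eligible), evaluable = any(eligible))
  if (!out$evaluable) {
    if (details) attr(out, "fits") <- f
    return(out)
  }
  best <- which(eligible)[which.min(f$bic[eligible])]
  pat <- patternTable(catalog)[f$pattern[best], ]
  out$pattern_id <- pat$pattern_id
  out$structure <- pat$structure
  out$orientation <- f$orientation[best]
  out$bic <- f$bic[best]
  out$logLik <- f$logLik[best]
  out$k <- f$k[best]
  out$p_pair <- if (pMethod == "wald") f$p_int[best] else
    .lrtPpair(g1, g2, y, catalog, f, best)
  if (details) attr(out, "fits") <- f
  out
}

## 1-df LRT of the selected design against the same design without its
## interaction column.
.lrtPpair <- function(g1, g2, y, catalog, fits, best) {
  plan <- .scanPlan(catalog)
  idx <- plan$designs[[best]]
  reduced <- idx[-length(idx)]
  ll0 <- if (length(reduced) == 0L) .nullLogLik(y) else {
    bank <- .bankFor(g1, g2)
    f0 <- fitLogistic(cbind(1, bank[, reduced, drop = FALSE]), y)
    f0$logLik
  }
  stat <- 2 * (fits$logLik[best] - ll0)
  pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

#' Additive-additive full-model interaction test (AA-Full)
#'
#' The conventional comparator: a single logistic fit
#' `y ~ g1 + g2 + g1:g2` with both SNPs coded additively, returning the Wald
#' p-value of the interaction term.
#'
#' @inheritParams sipiPair
#' @return list with `p` (interaction p-value), `coefficients`, and the fit
#'   flags of [fitLogistic()].
#' @export
aaFull <- function(g1, g2, y) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("genotype columns must be non-constant")
  X <- cbind(`(Intercept)` = 1, g1 = g1, g2 = g2, g1xg2 = g1 * g2)
  if (length(unique(g1 * g2)) < 2L)
    return(list(p = NA_real_, coefficients = NULL, degenerate = TRUE,
                converged = FALSE, separated = FALSE))
  f <- fitLogistic(X, y)
  list(p = if (f$degenerate) NA_real_ else unname(f$p["g1xg2"]),
       coefficients = f$coefficients, degenerate = f$degenerate,
       converged = f$converged, separated = f$separated)
}
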