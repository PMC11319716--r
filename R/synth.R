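## Synthetic genotype/phenotype generators: Hardy-Weinberg null SNPs and
## causal interaction pairs whose interaction-only logistic signal is
## calibrated to a target p-value at a reference sample size.

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @return probabilities of genotypes (0, 1, 2): `((1-q)^2, 2q(1-q), q^2)`.
#' @examples
#' hweProbs(0.1)  # 0.81 0.18 0.01
#' @export
hweProbs <- function(maf) {
  if (length(maf) != 1L || !is.finite(maf) || maf < 0 || maf > 0.5)
    stop("maf must be a single value in [0, 0.5]")
  q <- maf
  c(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)
}

#' Simulate independent null SNPs under Hardy-Weinberg equilibrium
#'
#' Each SNP column is an independent multinomial draw with genotype
#' probabilities `hweProbs(maf)`; null SNPs are generated independently of
#' any outcome.
#'
#' @param n number of subjects.
#' @param mafs vector of minor allele frequencies, one per SNP.
#' @param seed optional integer seed.
#' @param ids optional SNP ids (default `N1`, `N2`, ...).
#' @return a [GenotypeExperiment-class] with `maf` and `role = "null"` in its
#'   SNP annotation.
#' @export
simulateNullSnps <- function(n, mafs, seed = NULL, ids = NULL) {
  if (length(mafs) < 1L) stop("at least one MAF is required")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- paste0("N", seq_along(mafs))
  g <- vapply(mafs, function(q) sample(0:2, n, replace = TRUE,
                                       prob = hweProbs(q)), integer(n))
  colnames(g) <- ids
  rownames(g) <- paste0("subj", seq_len(n))
  GenotypeExperiment(g, snpInfo = data.frame(maf = mafs, role = "null"))
}

#' Specification of a causal interaction pair
#'
#' Describes the generating model of one causal SNP pair: two Hardy-Weinberg
#' SNPs and a Bernoulli outcome whose log-odds is
#' `intercept + effect * z(g1, g2)`, where `z` is the interaction variable of
#' an interaction-only catalog pattern. When `intercept` is `NULL` it is
#' solved at generation time so that the marginal outcome prevalence equals
#' `prevalence`.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @param pattern an interaction-only pattern id from [enumeratePatterns()].
#' @param effect log-odds coefficient of the interaction variable (may be
#'   `NA` before calibration).
#' @param intercept optional fixed log-odds intercept.
#' @param targetPPair optional calibration target for the pair's interaction
#'   p-value at a reference sample size (see [calibrateEffect()]).
#' @param prevalence target outcome prevalence used when `intercept` is NULL.
#' @return a `causalPairSpec` list.
#' @export
causalPairSpec <- function(maf1, maf2, pattern = "int_Dom_Dom",
                           effect = NA_real_, intercept = NULL,
                           targetPPair = NULL, prevalence = 0.5) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5)
  pat <- patternTable(enumeratePatterns())
  i <- match(pattern, pat$pattern_id)
  if (is.na(i)) stop("unknown pattern id: ", pattern)
  if (pat$structure[i] != "int_only")
    stop("generating pattern must be interaction-only")
  structure(list(maf1 = maf1, maf2 = maf2, pattern = pattern,
                 effect = effect, intercept = intercept,
                 targetPPair = targetPPair, prevalence = prevalence),
            class = "causalPairSpec")
}

## interaction variable z over the 9 genotype cells of a spec's pattern,
## with the cells' joint HWE probabilities
.specCells <- function(spec) {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  z <- pairVariable(grid$g1, grid$g2, spec$pattern)
  p <- hweProbs(spec$maf1)[grid$g1 + 1L] * hweProbs(spec$maf2)[grid$g2 + 1L]
  list(z = z, p = p)
}

## intercept making the marginal prevalence equal spec$prevalence
.solveIntercept <- function(spec, effect) {
  cells <- .specCells(spec)
  f <- function(a) sum(cells$p / (1 + exp(-(a + effect * cells$z)))) -
    spec$prevalence
  uniroot(f, lower = -35, upper = 35, tol = 1e-10)$root
}

#' Simulate one causal SNP pair and its outcome
#'
#' Draws the two SNPs independently under Hardy-Weinberg equilibrium and the
#' outcome from `Bernoulli(plogis(intercept + effect * z))`, `z` the
#' generating pattern's interaction variable.
#'
#' @param n number of subjects.
#' @param spec a [causalPairSpec()] with a finite `effect`.
#' @param seed optional integer seed.
#' @param ids SNP ids for the two columns.
#' @return list with integer vectors `g1`, `g2`, binary `y`, and the
#'   `intercept` used.
#' @export
simulateCausalPair <- function(n, spec, seed = NULL, ids = c("C1", "C2")) {
  stopifnot(inherits(spec, "causalPairSpec"))
  if (!is.finite(spec$effect))
    stop("spec$effect is not set; run calibrateEffect() first")
  if (!is.null(seed)) set.seed(seed)
  g1 <- sample(0:2, n, replace = TRUE, prob = hweProbs(spec$maf1))
  g2 <- sample(0:2, n, replace = TRUE, prob = hweProbs(spec$maf2))
  a <- if (is.null(spec$intercept)) .solveIntercept(spec, spec$effect)
       else spec$intercept
  eta <- a + spec$effect * pairVariable(g1, g2, spec$pattern)
  if (!all(is.finite(eta))) stop("non-finite linear predictor")
  y <- rbinom(n, 1L, 1 / (1 + exp(-eta)))
  list(g1 = g1, g2 = g2, y = y, intercept = a, ids = ids)
}

## analytic median Wald p-value of the generating interaction term at sample
## size n, for an interaction-only generating model with coefficient b
.medianWaldP <- function(spec, b, n) {
  cells <- .specCells(spec)
  a <- .solveIntercept(spec, b)
  mu <- 1 / (1 + exp(-(a + b * cells$z)))
  w <- cells$p * mu * (1 - mu)
  I11 <- sum(w); I12 <- sum(w * cells$z); I22 <- sum(w * cells$z^2)
  det <- I11 * I22 - I12^2
  if (det <= 0) return(1)
  avar <- I11 / det              # [I^-1]_22, per subject
  ncp <- n * b^2 / avar
  pchisq(qchisq(0.5, df = 1, ncp = ncp), df = 1, lower.tail = FALSE)
}

#' Calibrate an interaction effect size to a target p-value
#'
#' Finds the log-odds interaction coefficient whose median interaction
#' p-value at the reference sample size equals `targetPPair`. The default
#' `"analytic"` method uses the Wald non-centrality of the generating
#' interaction-only model (monotone in the effect magnitude, solved by
#' root-finding on the log10 scale). `"mc"` instead bisects on the median of
#' the full pattern scan's `p_pair` over Monte-Carlo replicates.
#'
#' @param spec a [causalPairSpec()].
#' @param targetPPair target p-value in (0, 1); defaults to
#'   `spec$targetPPair`.
#' @param nRef reference sample size at which the target applies.
#' @param method `"analytic"` or `"mc"`.
#' @param nRep Monte-Carlo replicates per evaluation (method `"mc"`).
#' @param seed seed for method `"mc"`.
#' @return the spec with `effect` (and `targetPPair`) filled in.
#' @export
calibrateEffect <- function(spec, targetPPair = spec$targetPPair,
                            nRef = 20000L, method = c("analytic", "mc"),
                            nRep = 25L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "causalPairSpec"))
  if (is.null(targetPPair) || targetPPair <= 0 || targetPPair >= 1)
    stop("targetPPair must be in (0, 1)")
  medp <- if (method == "analytic") {
    function(b) .medianWaldP(spec, b, nRef)
  } else {
    function(b) {
      sp <- spec; sp$effect <- b
      set.seed(seed)
      median(vapply(seq_len(nRep), function(r) {
        d <- simulateCausalPair(nRef, sp)
        sipiPair(d$g1, d$g2, d$y)$p_pair
      }, 0))
    }
  }
  f <- function(b) log10(max(medp(b), 1e-320)) - log10(targetPPair)
  if (f(0) <= 0) {                      # target at or above the null median
    spec$effect <- 0
    spec$targetPPair <- targetPPair
    return(spec)
  }
  upper <- 0.25
  while (f(upper) > 0 && upper < 16) upper <- upper * 2
  if (f(upper) > 0)
    stop("calibration error: target p-value unreachable at nRef")
  spec$effect <- uniroot(f, lower = 0, upper = upper, tol = 1e-6)$root
  spec$targetPPair <- targetPPair
  spec
}
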