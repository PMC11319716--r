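# Shared fixtures built in code.

# small HWE genotype matrix (subjects x SNPs) with a pure-null outcome
makeNullData <- function(n = 300, mafs = c(0.3, 0.1, 0.4, 0.2), seed = 1) {
  set.seed(seed)
  g <- sapply(mafs, function(q) sample(0:2, n, TRUE, prob = hweProbs(q)))
  colnames(g) <- paste0("rs", seq_along(mafs))
  rownames(g) <- paste0("s", seq_len(n))
  list(g = g, y = rbinom(n, 1, 0.5), mafs = mafs)
}

# independent stats::glm refit of one ordered design, for oracle checks
glmRefit <- function(X, y) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- paste0("x", seq_len(ncol(d)))
  f <- stats::glm(y ~ ., data = d, family = stats::binomial(),
                  control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  list(logLik = as.numeric(stats::logLik(f)),
       bic = stats::BIC(f),
       p_last = stats::coef(summary(f))[nrow(stats::coef(summary(f))), 4],
       converged = f$converged,
       maxcoef = max(abs(stats::coef(f))))
}

# Every ordered design of the catalog for a concrete pair, refit via glm.
# Likelihoods, BICs and the argmin are recomputed independently; eligibility
# (converged, non-separated, non-degenerate) follows the package's documented
# fitting contract, since quasi-separation has no canonical glm-side
# definition to recover it from.
bruteForceBest <- function(g1, g2, y, catalog = enumeratePatterns()) {
  pt <- patternTable(catalog)
  best <- list(bic = Inf)
  for (i in seq_len(nrow(pt))) {
    for (o in if (pt$symmetric[i]) 1L else c(1L, 2L)) {
      X <- patternDesign(pt$pattern_id[i], g1, g2, orientation = o)
      if (qr(X)$rank < ncol(X)) next
      fl <- fitLogistic(X, y)
      if (!fl$converged || fl$separated || fl$degenerate) next
      f <- suppressWarnings(glmRefit(X, y))
      if (f$bic < best$bic)
        best <- list(bic = f$bic, pattern_id = pt$pattern_id[i],
                     orientation = o, p_last = f$p_last)
    }
  }
  best
}

tsvTmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
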