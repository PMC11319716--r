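#' Best-inheritance-mode main-effect test for one SNP
#'
#' Fits `y ~ coding(g)` for the additive, dominant and recessive codings
#' (original direction; the reverse direction is a monotone relabelling that
#' leaves the single-covariate Wald p-value unchanged) and reports the mode
#' with the smallest p-value. Codings that are degenerate on the data (for
#' example recessive when no minor-allele homozygote is present) are skipped.
#'
#' @param g genotype vector with values in `{0, 1, 2}`.
#' @param y binary 0/1 outcome.
#' @return list with `best_mode`, `p_main` and the named per-mode p-value
#'   vector `p_modes`.
#' @examples
#' g <- sample(0:2, 500, TRUE, c(0.49, 0.42, 0.09))
#' y <- rbinom(500, 1, 0.5)
#' snpMain(g, y)$p_main
#' @export
snpMain <- function(g, y) {
  g <- as.integer(g)
  if (!all(g %in% c(0L, 1L, 2L)))
    stop("invalid genotype: entries must be 0, 1 or 2")
  if (length(unique(g)) < 2L)
    stop("genotype column is constant")
  y <- as.numeric(y)
  modes <- c("additive", "dominant", "recessive")
  p <- setNames(rep(NA_real_, 3L), modes)
  for (m in modes) {
    x <- applyCoding(g, m)
    if (length(unique(x)) < 2L) next
    f <- fitLogistic(cbind(1, x), y)
    if (f$degenerate || !f$converged || f$separated) next
    p[[m]] <- f$p[2L]
  }
  if (all(is.na(p))) stop("all inheritance-mode codings are degenerate")
  best <- names(p)[which.min(p)]
  list(best_mode = best, p_main = unname(p[best]), p_modes = p)
}

## p_main for every column of a SNPs-in-rows genotype matrix; NA where the
## test is undefined (constant column or all codings degenerate).
.mainEffects <- function(gmat, y) {
  vapply(seq_len(nrow(gmat)), function(i) {
    g <- gmat[i, ]
    ok <- !is.na(g) & !is.na(y)
    if (length(unique(g[ok])) < 2L) return(NA_real_)
    res <- tryCatch(snpMain(g[ok], y[ok]), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$p_main
  }, 0)
}
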