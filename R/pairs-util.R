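#' Number of unordered SNP pairs
#'
#' @param m integer number of SNPs, `m >= 2`.
#' @return `m * (m - 1) / 2`.
#' @examples
#' countPairs(614)  # 188191
#' @export
countPairs <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 2 || m != floor(m))
    stop("m must be a single integer >= 2")
  m * (m - 1) / 2
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param n_tests number of tests, `>= 1`.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroniThreshold(0.05, 614)              # ~8.1e-5
#' bonferroniThreshold(0.05, countPairs(614))  # ~2.7e-7
#' @export
bonferroniThreshold <- function(alpha, n_tests) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (length(n_tests) != 1L || !is.finite(n_tests) || n_tests < 1 ||
      n_tests != floor(n_tests))
    stop("n_tests must be a single integer >= 1")
  alpha / n_tests
}

## All unordered index pairs from m SNPs as a 2-column integer matrix.
.allPairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])[order(idx[, "row"], idx[, "col"]),
                                            , drop = FALSE]
}
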