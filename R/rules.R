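#' Significance rules for interaction pairs
#'
#' `1pRule` declares a pair significant when `p_pair < criterion`. `3pRule`
#' additionally requires the interaction to beat both composite SNPs' main
#' effects: `p_pair < p_main1` and `p_pair < p_main2`. All comparisons are
#' strict, so the two rules can only disagree when at least one `p_main` is
#' below the criterion. Vectorised over pairs.
#'
#' @param p_pair interaction p-value(s).
#' @param p_main1,p_main2 best-mode main-effect p-values of the two SNPs
#'   (ignored under `1pRule`).
#' @param criterion the p-pair criterion, e.g. a Bonferroni threshold.
#' @param rule `"3pRule"` or `"1pRule"`.
#' @return logical vector of significance flags (`NA` p_pair gives `FALSE`).
#' @examples
#' evalRule(5.7e-18, 2.2e-15, 0.027, criterion = 2.7e-7)       # TRUE
#' evalRule(1e-8, 1e-10, 0.5, criterion = 2.7e-7)              # FALSE
#' evalRule(1e-8, 1e-10, 0.5, criterion = 2.7e-7, rule = "1pRule")  # TRUE
#' @export
evalRule <- function(p_pair, p_main1 = NULL, p_main2 = NULL, criterion,
                     rule = c("3pRule", "1pRule")) {
  rule <- match.arg(rule)
  stopifnot(length(criterion) == 1L, criterion > 0, criterion < 1)
  ok <- !is.na(p_pair) & p_pair < criterion
  if (rule == "3pRule") {
    if (is.null(p_main1) || is.null(p_main2))
      stop("3pRule needs both p_main values")
    ok <- ok & !is.na(p_main1) & p_pair < p_main1 &
               !is.na(p_main2) & p_pair < p_main2
  }
  ok
}
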