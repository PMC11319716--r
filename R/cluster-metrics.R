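## Cluster-effect diagnostics: interaction variables, pair/LD correlations
## and positivity metrics (TIR/FIR for simulation replicates, TPR/FPR and
## cluster-level FPR for the hybrid layout).

#' Interaction variable of a pattern for a concrete pair
#'
#' The elementwise product of the two coded genotype columns — the covariate
#' carrying the pair's interaction. Additive x additive coding yields values
#' in `{0, 1, 2, 4}`; binary x binary codings yield a 0/1 vector.
#'
#' @inheritParams patternDesign
#' @return numeric vector of the interaction term.
#' @examples
#' pairVariable(2, 2, "int_Add_Add")  # 4
#' @export
pairVariable <- function(g1, g2, pattern_id, orientation = 1L,
                         catalog = enumeratePatterns()) {
  X <- patternDesign(pattern_id, g1, g2, orientation = orientation,
                     catalog = catalog)
  unname(X[, ncol(X)])
}

#' Correlation between two pair interaction variables
#'
#' Pearson correlation; when both vectors are binary 0/1 this is the Phi
#' coefficient (identical formula).
#'
#' @param v1,v2 numeric vectors of equal length, both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pairCorrelation <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  if (length(unique(v1)) < 2L || length(unique(v2)) < 2L)
    stop("undefined correlation: constant vector")
  cor(v1, v2)
}

#' Composite linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages; values above 0.8 are
#' conventionally called strong LD.
#'
#' @param g1,g2 genotype dosage vectors, both non-constant.
#' @return squared correlation in `[0, 1]`.
#' @export
ldR2 <- function(g1, g2) {
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("undefined r^2: constant genotype column")
  cor(g1, g2)^2
}

#' Spearman correlation between p_pair and the stronger p_main
#'
#' Rank correlation between each pair's interaction p-value and the smaller
#' of its two main-effect p-values ("the most significant composite SNP").
#'
#' @param results a scan data.frame with `p_main1`, `p_main2` and the column
#'   named by `column`.
#' @param column p-value column to correlate (`"p_pair"` or `"p_aa_full"`).
#' @return list with `rho` and `p`.
#' @export
ppairPmainCorrelation <- function(results, column = "p_pair") {
  pp <- results[[column]]
  pm <- pmin(results$p_main1, results$p_main2)
  ok <- !is.na(pp) & !is.na(pm)
  if (sum(ok) < 3L) stop("at least 3 pairs are required")
  ct <- cor.test(pp[ok], pm[ok], method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Positivity rates from flagged scan results
#'
#' For `type = "hybrid"` (one dataset, `class` column from
#' [classifyPairs()]): the true positive rate over designated causal pairs,
#' the false positive rate over all null pairs and per-class significant
#' counts, for each rule. For `type = "simulation"` (stacked replicates with
#' a `run` column and `class` in `"C-C"`/`"C-N"`): the true/false
#' identification rates TIR/FIR pooled over replicates, with a per-MAF FIR
#' breakdown when a `maf` column describes the peripheral null SNP.
#'
#' @param results flagged pair results (`sig_1p`, `sig_3p` columns).
#' @param type `"hybrid"` or `"simulation"`.
#' @return list of rates (proportions in `[0, 1]`); see Details.
#' @export
computeRates <- function(results, type = c("hybrid", "simulation")) {
  type <- match.arg(type)
  if (!all(c("sig_1p", "sig_3p") %in% names(results)))
    stop("results must carry sig_1p and sig_3p flags")
  if (is.null(results$class)) stop("results must carry a class column")
  if (type == "hybrid") {
    causal <- results$class == "C-C"
    if (!any(causal) || !any(!causal))
      stop("undefined metric: empty causal or null set")
    counts <- lapply(c(sig_1p = "sig_1p", sig_3p = "sig_3p"), function(s)
      tapply(results[[s]], results$class, sum))
    list(tpr_1p = mean(results$sig_1p[causal]),
         tpr_3p = mean(results$sig_3p[causal]),
         fpr_1p = mean(results$sig_1p[!causal], na.rm = TRUE),
         fpr_3p = mean(results$sig_3p[!causal], na.rm = TRUE),
         n_causal = sum(causal), n_null = sum(!causal),
         counts_1p = counts$sig_1p, counts_3p = counts$sig_3p)
  } else {
    if (is.null(results$run)) stop("simulation results need a run column")
    causal <- results$class == "C-C"
    if (!any(causal) || !any(!causal))
      stop("undefined metric: empty causal or null set")
    out <- list(tir_1p = mean(results$sig_1p[causal]),
                tir_3p = mean(results$sig_3p[causal]),
                fir_1p = mean(results$sig_1p[!causal]),
                fir_3p = mean(results$sig_3p[!causal]),
                n_runs = length(unique(results$run)),
                n_causal = sum(causal), n_null = sum(!causal))
    if (!is.null(results$maf)) {
      nul <- results[!causal, ]
      out$fir_by_maf <- data.frame(
        maf = sort(unique(nul$maf)),
        fir_1p = as.numeric(tapply(nul$sig_1p, nul$maf, mean)),
        fir_3p = as.numeric(tapply(nul$sig_3p, nul$maf, mean)))
    }
    out
  }
}

#' Cluster-level false positive rate for a hub SNP
#'
#' The proportion of significant calls among the null pairs sharing the hub
#' SNP, per rule, with a per-MAF breakdown when `snpInfo` provides the
#' peripheral null SNPs' MAFs.
#'
#' @param results classified scan results (see [classifyPairs()]).
#' @param hub hub SNP id.
#' @param snpInfo optional data.frame with rownames = SNP ids and a `maf`
#'   column.
#' @return list with `fpr_1p`, `fpr_3p`, `n_pairs` and optionally
#'   `by_maf`.
#' @export
fprCluster <- function(results, hub, snpInfo = NULL) {
  inCluster <- (results$snp1 == hub | results$snp2 == hub) &
    results$class != "C-C"
  if (!any(inCluster)) stop("undefined metric: hub has no null pairs")
  sub <- results[inCluster, ]
  out <- list(hub = hub,
              fpr_1p = mean(sub$sig_1p, na.rm = TRUE),
              fpr_3p = mean(sub$sig_3p, na.rm = TRUE),
              n_pairs = nrow(sub))
  if (!is.null(snpInfo) && "maf" %in% names(snpInfo)) {
    other <- ifelse(sub$snp1 == hub, sub$snp2, sub$snp1)
    maf <- snpInfo[other, "maf"]
    ok <- !is.na(maf)
    if (any(ok))
      out$by_maf <- data.frame(
        maf = sort(unique(maf[ok])),
        fpr_1p = as.numeric(tapply(sub$sig_1p[ok], maf[ok], mean)),
        fpr_3p = as.numeric(tapply(sub$sig_3p[ok], maf[ok], mean)),
        n = as.integer(table(maf[ok])))
  }
  out
}

#' Correlations between a causal pair and its cluster's significant null pairs
#'
#' For every significant null pair sharing the hub SNP, the correlation
#' between the causal pair's selected interaction variable and the null
#' pair's selected interaction variable (Pearson; the Phi coefficient when
#' both variables are binary).
#'
#' @param x a [GenotypeExperiment-class] holding the scanned genotypes.
#' @param results classified scan results carrying `pattern_id` and
#'   `orientation`.
#' @param hub hub SNP id.
#' @param causalPair length-2 character vector, the cluster's causal pair.
#' @param rule rule whose significance flags select the null pairs.
#' @return data.frame with one row per significant null pair: the peripheral
#'   SNP, its MAF when annotated, and `corr`.
#' @export
clusterCorrelations <- function(x, results, hub, causalPair,
                                rule = c("3pRule", "1pRule")) {
  rule <- match.arg(rule)
  sigCol <- if (rule == "3pRule") "sig_3p" else "sig_1p"
  gmat <- genotypes(x)
  cc <- results[(results$snp1 %in% causalPair & results$snp2 %in% causalPair), ]
  if (nrow(cc) != 1L || is.na(cc$pattern_id))
    stop("causal pair not found in results")
  vCausal <- pairVariable(gmat[cc$snp1, ], gmat[cc$snp2, ], cc$pattern_id,
                          cc$orientation)
  sel <- results[(results$snp1 == hub | results$snp2 == hub) &
                   results$class != "C-C" & results[[sigCol]] %in% TRUE, ]
  info <- snpInfo(x)
  rows <- lapply(seq_len(nrow(sel)), function(r) {
    peripheral <- if (sel$snp1[r] == hub) sel$snp2[r] else sel$snp1[r]
    v <- pairVariable(gmat[sel$snp1[r], ], gmat[sel$snp2[r], ],
                      sel$pattern_id[r], sel$orientation[r])
    data.frame(peripheral = peripheral,
               maf = if ("maf" %in% names(info)) info[peripheral, "maf"]
                     else NA_real_,
               corr = pairCorrelation(vCausal, v))
  })
  if (length(rows) == 0L)
    return(data.frame(peripheral = character(), maf = numeric(),
                      corr = numeric()))
  do.call(rbind, rows)
}
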