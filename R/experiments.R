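## Study layouts and orchestration: hub-SNP clusters (one causal pair plus
## six peripheral null SNPs) and the 614-SNP hybrid layout (7 causal pairs
## plus 600 null SNPs), with end-to-end drivers.

.NULL_MAFS <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Default causal-pair generating specifications
#'
#' `part1Specs()` returns the four simulation-study interaction sets at the
#' chosen significance levels; each set pairs a generating interaction-only
#' pattern with fixed MAFs, and each level carries the target interaction
#' p-value (at n = 20,000) its effect size is calibrated to. The set-1
#' targets are 4.5e-18 / 9.1e-14 / 1.6e-8 for high / medium / low; remaining
#' targets are package defaults spanning the same significance range.
#' `part2Specs()` returns the seven hybrid-study pair specifications whose
#' MAFs (0.06-0.46) and target p-pairs (5.7e-18 to 3.4e-9) emulate the seven
#' observed causal pairs.
#'
#' @param sets which of the four interaction sets to include.
#' @param levels significance levels: `"H"`, `"M"`, `"L"`.
#' @return list of [causalPairSpec()] objects (uncalibrated).
#' @export
part1Specs <- function(sets = 1:4, levels = c("H", "M", "L")) {
  base <- list(
    list(maf = c(0.055, 0.31), pattern = "int_Dom_Dom",
         target = c(H = 4.5e-18, M = 9.1e-14, L = 1.6e-8)),
    list(maf = c(0.12, 0.444), pattern = "int_Add_Add",
         target = c(H = 3.9e-13, M = 1.0e-9, L = 1.0e-6)),
    list(maf = c(0.15, 0.28), pattern = "int_Add_Dom",
         target = c(H = 1.0e-8, M = 1.0e-6, L = 1.0e-4)),
    list(maf = c(0.35, 0.16), pattern = "int_Dom_Rec",
         target = c(H = 6.7e-5, M = 1.0e-3, L = 1.0e-2)))
  out <- list()
  for (s in sets) for (lv in levels) {
    b <- base[[s]]
    out[[paste0("C", 2 * s - 1, "C", 2 * s, "_", lv)]] <-
      causalPairSpec(b$maf[1], b$maf[2], pattern = b$pattern,
                     targetPPair = unname(b$target[lv]))
  }
  out
}

#' @rdname part1Specs
#' @export
part2Specs <- function() {
  maf1 <- c(0.06, 0.12, 0.15, 0.46, 0.11, 0.35, 0.24)
  maf2 <- c(0.31, 0.44, 0.28, 0.14, 0.26, 0.31, 0.16)
  target <- c(5.7e-18, 4.4e-13, 8.5e-10, 2.3e-9, 3.5e-10, 1.7e-12, 3.4e-9)
  pattern <- c("int_Dom_Dom", "int_Add_Add", "int_Add_Dom", "int_Add_Add",
               "int_Dom_Dom", "int_Add_Add", "int_Add_Dom")
  lapply(seq_len(7L), function(i)
    causalPairSpec(maf1[i], maf2[i], pattern = pattern[i],
                   targetPPair = target[i]))
}

#' Build one hub-SNP cluster dataset
#'
#' One causal pair (with its simulated outcome) plus six independent
#' peripheral null SNPs at the given MAFs. The evaluated pairs are the
#' causal pair and the hub SNP paired with each null SNP.
#'
#' @param spec a calibrated [causalPairSpec()].
#' @param n number of subjects.
#' @param hub which causal SNP (1 or 2) is the cluster hub.
#' @param nullMafs MAFs of the peripheral null SNPs.
#' @param seed optional integer seed.
#' @return list with `data` (a [GenotypeExperiment-class] of 8 SNPs with
#'   phenotype), `pairs` (7 x 2 id matrix) and `hub` (the hub SNP id).
#' @export
buildPart1Cluster <- function(spec, n, hub = 1L, nullMafs = .NULL_MAFS,
                              seed = NULL) {
  if (length(nullMafs) != 6L) stop("six peripheral null MAFs are required")
  if (!is.null(seed)) set.seed(seed)
  cp <- simulateCausalPair(n, spec)
  nul <- simulateNullSnps(n, nullMafs)
  g <- cbind(C1 = cp$g1, C2 = cp$g2, t(genotypes(nul)))
  info <- data.frame(
    maf = c(spec$maf1, spec$maf2, nullMafs),
    role = c("causal", "causal", rep("null", 6L)),
    row.names = colnames(g))
  ge <- GenotypeExperiment(g, phenotype = cp$y, snpInfo = info)
  hubId <- c("C1", "C2")[hub]
  pairs <- rbind(c("C1", "C2"),
                 cbind(hubId, rownames(nul)))
  list(data = ge, pairs = unname(pairs), hub = hubId)
}

#' Build the hybrid-study dataset
#'
#' Generates the 614-SNP layout: 14 causal SNPs from 7 interaction pairs
#' (effects calibrated to their target p-values at `nRef`, all contributing
#' to one logistic outcome at overall prevalence 0.5) plus `nullPerMaf`
#' independent Hardy-Weinberg null SNPs at each of the six MAFs.
#'
#' @param n number of subjects.
#' @param specs list of 7 causal-pair specifications (default
#'   [part2Specs()]); calibrated automatically when effects are unset.
#' @param nullPerMaf null SNPs per MAF condition (default 100, i.e. 600).
#' @param nullMafs the null-SNP MAF grid.
#' @param nRef reference sample size for calibration.
#' @param seed optional integer seed.
#' @return list with `data` (a [GenotypeExperiment-class] with phenotype and
#'   SNP annotation) and `causalPairs` (7 x 2 id matrix).
#' @export
buildPart2Dataset <- function(n = 20000L, specs = part2Specs(),
                              nullPerMaf = 100L, nullMafs = .NULL_MAFS,
                              nRef = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- lapply(specs, function(sp) {
    if (is.finite(sp$effect)) sp else calibrateEffect(sp, nRef = nRef)
  })
  nPairs <- length(specs)
  ## genotypes of the causal SNPs
  gC <- matrix(0L, nrow = n, ncol = 2L * nPairs)
  ids <- unlist(lapply(seq_len(nPairs), function(i) paste0("C", c(2*i-1, 2*i))))
  colnames(gC) <- ids
  eta <- rep(0, n)
  for (i in seq_len(nPairs)) {
    sp <- specs[[i]]
    g1 <- sample(0:2, n, replace = TRUE, prob = hweProbs(sp$maf1))
    g2 <- sample(0:2, n, replace = TRUE, prob = hweProbs(sp$maf2))
    gC[, 2*i - 1] <- g1; gC[, 2*i] <- g2
    eta <- eta + sp$effect * pairVariable(g1, g2, sp$pattern)
  }
  ## one shared outcome: intercept set so realized prevalence targets 0.5
  a <- uniroot(function(a) mean(1 / (1 + exp(-(a + eta)))) - 0.5,
               lower = -35, upper = 35, tol = 1e-10)$root
  y <- rbinom(n, 1L, 1 / (1 + exp(-(a + eta))))

  mafsNull <- rep(nullMafs, each = nullPerMaf)
  nul <- simulateNullSnps(n, mafsNull,
                          ids = paste0("N", seq_along(mafsNull)))
  g <- cbind(gC, t(genotypes(nul)))
  info <- data.frame(
    maf = c(unlist(lapply(specs, function(s) c(s$maf1, s$maf2))), mafsNull),
    role = c(rep("causal", 2L * nPairs), rep("null", length(mafsNull))),
    row.names = colnames(g))
  ge <- GenotypeExperiment(g, phenotype = y, snpInfo = info)
  causalPairs <- t(vapply(seq_len(nPairs),
                          function(i) c(paste0("C", 2*i - 1), paste0("C", 2*i)),
                          c("", "")))
  list(data = ge, causalPairs = causalPairs, specs = specs, intercept = a)
}

#' Run the cluster simulation study
#'
#' For each causal-pair specification and each replicate: build a hub-SNP
#' cluster dataset, scan its 7 pairs, and flag them under both rules; then
#' pool replicates into TIR/FIR (with per-MAF FIR). Scales freely — the full
#' design is 24 clusters x 1000 runs x n up to 20,000, but any subset runs.
#'
#' @param specs named list of causal-pair specs (see [part1Specs()]);
#'   calibrated automatically when needed (targets apply at `nRef`).
#' @param n subjects per replicate.
#' @param nRuns replicates per condition.
#' @param hub which causal SNP is the hub (1 or 2).
#' @param criterion the p-pair criterion (the simulation-study default is
#'   1e-4; the pairwise Bonferroni threshold 2.7e-7 is the stricter
#'   alternative).
#' @param nRef calibration reference sample size.
#' @param seed integer root seed; per-replicate seeds are derived from it.
#' @param nullMafs peripheral null MAF grid.
#' @return list with `summary` (one row per condition and rule: TIR, FIR)
#'   and `perMaf` (FIR by peripheral MAF), plus the raw flagged results.
#' @export
runPart1 <- function(specs = part1Specs(sets = 1, levels = "H"), n = 5000L,
                     nRuns = 100L, hub = 1L, criterion = 1e-4,
                     nRef = 20000L, seed = 1L, nullMafs = .NULL_MAFS) {
  specs <- lapply(specs, function(sp)
    if (is.finite(sp$effect)) sp else calibrateEffect(sp, nRef = nRef))
  set.seed(seed)
  repSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                length(specs) * nRuns),
                     nrow = length(specs))
  all <- list()
  for (s in seq_along(specs)) {
    cond <- names(specs)[s]
    if (is.null(cond)) cond <- paste0("spec", s)
    for (r in seq_len(nRuns)) {
      cl <- buildPart1Cluster(specs[[s]], n = n, hub = hub,
                              nullMafs = nullMafs, seed = repSeeds[s, r])
      sc <- scanPairs(cl$data, pairs = cl$pairs, criterion = criterion)
      sc$run <- r
      sc$condition <- cond
      sc$class <- ifelse(sc$snp1 %in% c("C1", "C2") &
                           sc$snp2 %in% c("C1", "C2"), "C-C", "C-N")
      info <- snpInfo(cl$data)
      peripheral <- ifelse(sc$class == "C-N",
                           ifelse(sc$snp1 == cl$hub, sc$snp2, sc$snp1), NA)
      sc$maf <- ifelse(is.na(peripheral), NA_real_, info[peripheral, "maf"])
      all[[length(all) + 1L]] <- sc
    }
  }
  res <- do.call(rbind, all)
  summary <- do.call(rbind, lapply(split(res, res$condition), function(d) {
    rt <- computeRates(d, type = "simulation")
    data.frame(condition = d$condition[1], tir_1p = rt$tir_1p,
               tir_3p = rt$tir_3p, fir_1p = rt$fir_1p, fir_3p = rt$fir_3p,
               n_runs = rt$n_runs, row.names = NULL)
  }))
  perMaf <- do.call(rbind, lapply(split(res, res$condition), function(d) {
    rt <- computeRates(d, type = "simulation")
    cbind(condition = d$condition[1], rt$fir_by_maf)
  }))
  rownames(perMaf) <- NULL
  list(summary = summary, perMaf = perMaf, results = res,
       criterion = criterion, n = n, nRuns = nRuns)
}

#' Run the hybrid study
#'
#' Builds (or accepts) a hybrid dataset, scans the requested pairs, computes
#' TPR/FPR and per-hub cluster FPRs, and optionally adds bootstrap selection
#' frequencies. The full layout has 188,191 pairs; `nNullPairs` caps the
#' number of scanned null-null pairs (sampled reproducibly) so reduced runs
#' stay tractable while every causal-involved pair is always scanned.
#'
#' @param dataset optional result of [buildPart2Dataset()]; built when NULL.
#' @param n,specs,seed passed to [buildPart2Dataset()] when building.
#' @param criterion p-pair criterion; default the pairwise Bonferroni
#'   threshold for the full pair count of the dataset.
#' @param nNullPairs optional cap on scanned N-N pairs.
#' @param B bootstrap replicates (0 = no bootstrap).
#' @param thresholds bootstrap selection-frequency thresholds.
#' @return list with classified `results`, `rates`, per-hub `clusters`,
#'   and optionally `bootstrap`.
#' @export
runPart2 <- function(dataset = NULL, n = 20000L, specs = part2Specs(),
                     seed = 1L, criterion = NULL, nNullPairs = NULL,
                     B = 0L, thresholds = c(0.75, 0.80, 0.85, 0.90)) {
  if (is.null(dataset))
    dataset <- buildPart2Dataset(n = n, specs = specs, seed = seed)
  ge <- dataset$data
  info <- snpInfo(ge)
  roles <- setNames(info$role, rownames(info))
  m <- nrow(ge)
  pairsIdx <- .allPairs(m)
  ids <- rownames(ge)
  if (!is.null(nNullPairs)) {
    isNull <- roles[ids[pairsIdx[, 1]]] == "null" &
              roles[ids[pairsIdx[, 2]]] == "null"
    keep <- which(!isNull)
    nn <- which(isNull)
    set.seed(seed + 1L)
    keep <- sort(c(keep, sample(nn, min(nNullPairs, length(nn)))))
    pairsIdx <- pairsIdx[keep, , drop = FALSE]
  }
  if (is.null(criterion))
    criterion <- bonferroniThreshold(0.05, countPairs(m))
  res <- scanPairs(ge, pairs = pairsIdx, criterion = criterion)
  res <- classifyPairs(res, roles, dataset$causalPairs)
  rates <- computeRates(res, type = "hybrid")
  hubs <- unique(as.vector(dataset$causalPairs))
  clusters <- lapply(setNames(hubs, hubs), function(h)
    fprCluster(res, h, snpInfo = info))
  out <- list(results = res, rates = rates, clusters = clusters,
              criterion = criterion, dataset = dataset)
  if (B > 0L) {
    out$bootstrap <- boot3p(ge, pairs = pairsIdx, criterion = criterion,
                            B = B, thresholds = thresholds, seed = seed)
  }
  out
}
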