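test_that("hybrid rates reduce to the documented arithmetic", {
  # a hub with 600 null pairs, 232 significant -> cluster FPR 38.7%
  res <- data.frame(
    snp1 = "hub", snp2 = paste0("N", 1:600),
    sig_1p = c(rep(TRUE, 291), rep(FALSE, 309)),
    sig_3p = c(rep(TRUE, 232), rep(FALSE, 368)),
    class = "C-N", stringsAsFactors = FALSE)
  fc <- fprCluster(res, "hub")
  expect_equal(round(100 * fc$fpr_3p, 1), 38.7)
  expect_equal(fc$n_pairs, 600L)

  # 7 of 7 causal pairs significant -> TPR 100%
  res2 <- rbind(res,
                data.frame(snp1 = "hub", snp2 = paste0("C", 1:7),
                           sig_1p = TRUE, sig_3p = TRUE, class = "C-C"))
  rt <- computeRates(res2, type = "hybrid")
  expect_equal(rt$tpr_3p, 1)
  expect_equal(rt$fpr_3p, 232 / 600)
  expect_equal(unname(rt$counts_3p["C-N"]), 232)
})

test_that("simulation rates pool replicates as defined", {
  # 6 null pairs x 1000 runs with 1230 significant flags -> FIR 20.5%
  grid <- expand.grid(run = 1:1000, pair = 1:6)
  sig <- rep(FALSE, 6000); sig[seq_len(1230)] <- TRUE
  res <- data.frame(run = grid$run, snp1 = "hub",
                    snp2 = paste0("N", grid$pair),
                    sig_1p = sig, sig_3p = sig, class = "C-N",
                    maf = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)[grid$pair],
                    stringsAsFactors = FALSE)
  causal <- data.frame(run = 1:1000, snp1 = "hub", snp2 = "C2",
                       sig_1p = TRUE, sig_3p = rep(c(TRUE, FALSE), c(909, 91)),
                       class = "C-C", maf = NA_real_)
  rt <- computeRates(rbind(res, causal), type = "simulation")
  expect_equal(round(100 * rt$fir_1p, 1), 20.5)
  expect_equal(rt$tir_3p, 0.909)
  expect_equal(rt$n_runs, 1000L)
  expect_equal(nrow(rt$fir_by_maf), 6L)
  # rates times counts give back integer flag totals
  expect_equal(rt$fir_1p * rt$n_null, 1230)
  expect_equal(rt$tir_3p * rt$n_causal, 909)
  expect_error(computeRates(res, type = "simulation"), "undefined metric")
})

test_that("pair correlation is Pearson, and Phi equals Pearson on binaries", {
  set.seed(51)
  b1 <- rbinom(500, 1, 0.4)
  expect_equal(pairCorrelation(b1, b1), 1)
  b2 <- rbinom(500, 1, 0.3)
  phi <- pairCorrelation(b1, b2)
  # explicit Phi formula from the 2x2 table
  tab <- table(factor(b1, 0:1), factor(b2, 0:1))
  phi2 <- (tab[2, 2] * tab[1, 1] - tab[2, 1] * tab[1, 2]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  expect_equal(phi, unname(phi2), tolerance = 1e-12)
  # independent variables at large n: correlation near zero
  expect_lt(abs(pairCorrelation(rbinom(1e5, 1, 0.3), rbinom(1e5, 1, 0.4))),
            0.02)
  expect_error(pairCorrelation(rep(1, 10), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("LD r-squared behaves as composite dosage correlation", {
  set.seed(52)
  g1 <- sample(0:2, 1e5, TRUE, hweProbs(0.3))
  g2 <- sample(0:2, 1e5, TRUE, hweProbs(0.2))
  expect_equal(ldR2(g1, g1), 1)
  expect_equal(ldR2(g1, g2), ldR2(g2, g1))
  # independently simulated SNPs: r2 ~ 0 (the observed range is 0-0.0004)
  expect_lt(ldR2(g1, g2), 0.001)
  expect_error(ldR2(rep(0, 10), g2[1:10]), "constant")
})

test_that("p_pair/p_main rank correlation is monotone-invariant", {
  res <- data.frame(p_pair = c(1e-9, 1e-7, 1e-5, 1e-3, 0.05, 0.3),
                    p_main1 = c(1e-8, 1e-6, 1e-4, 1e-2, 0.1, 0.6),
                    p_main2 = 0.9)
  r <- ppairPmainCorrelation(res)
  expect_equal(r$rho, 1)
  res2 <- transform(res, p_pair = sqrt(p_pair), p_main1 = p_main1^2)
  expect_equal(ppairPmainCorrelation(res2)$rho, 1)
  expect_error(ppairPmainCorrelation(res[1:2, ]), "3 pairs")
})

test_that("cluster correlations track the causal pair's interaction variable", {
  sp <- calibrateEffect(causalPairSpec(0.3, 0.25, pattern = "int_Dom_Dom"),
                        targetPPair = 1e-12, nRef = 3000)
  cl <- buildPart1Cluster(sp, n = 3000, seed = 53)
  sc <- scanPairs(cl$data, pairs = cl$pairs, criterion = 1e-3)
  sc$class <- ifelse(sc$snp2 == "C2", "C-C", "C-N")
  cc <- clusterCorrelations(cl$data, sc, hub = "C1",
                            causalPair = c("C1", "C2"))
  expect_true(all(abs(cc$corr) <= 1))
  if (nrow(cc) > 0) expect_true(all(cc$peripheral %in% paste0("N", 1:6)))
})
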