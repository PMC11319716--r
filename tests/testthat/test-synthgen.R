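test_that("Hardy-Weinberg probabilities follow the closed form", {
  expect_equal(unname(hweProbs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hweProbs(0)), c(1, 0, 0))
  expect_equal(unname(hweProbs(0.1)), c(0.81, 0.18, 0.01))
  q <- 0.37
  expect_equal(sum(hweProbs(q)), 1)
  expect_equal(unname(hweProbs(q)), c((1 - q)^2, 2 * q * (1 - q), q^2))
  expect_error(hweProbs(0.6), "maf")
  expect_error(hweProbs(-0.1), "maf")
})

test_that("simulated null SNPs pass a goodness-of-fit test against HWE", {
  ge <- simulateNullSnps(1e5, c(0.05, 0.3, 0.5), seed = 41)
  g <- genotypes(ge)
  for (i in 1:3) {
    obs <- tabulate(g[i, ] + 1L, nbins = 3L)
    expected <- hweProbs(snpInfo(ge)$maf[i])
    gof <- stats::chisq.test(obs, p = expected)
    expect_gt(gof$p.value, 0.001)
    # empirical minor-allele frequency stays at or below one half
    expect_lte(mean(g[i, ]) / 2, 0.5 + 0.01)
  }
})

test_that("null-SNP simulation is reproducible and correctly shaped", {
  a <- simulateNullSnps(200, rep(c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), 3),
                        seed = 42)
  b <- simulateNullSnps(200, rep(c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), 3),
                        seed = 42)
  expect_identical(genotypes(a), genotypes(b))
  expect_equal(dim(a), c(18L, 200L))
  expect_true(all(snpInfo(a)$role == "null"))
})

test_that("a zero effect leaves the outcome independent of the genotypes", {
  sp <- causalPairSpec(0.3, 0.2, pattern = "int_Dom_Dom", effect = 0)
  set.seed(43)
  ps <- replicate(200, {
    d <- simulateCausalPair(300, sp)
    z <- pairVariable(d$g1, d$g2, sp$pattern)
    fitLogistic(cbind(1, z), d$y)$p[2]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  d <- simulateCausalPair(5000, sp, seed = 44)
  expect_equal(mean(d$y), 0.5, tolerance = 0.05)
})

test_that("calibration hits its targets and is monotone", {
  base <- causalPairSpec(0.055, 0.31, pattern = "int_Dom_Dom")
  # null target: no effect needed
  expect_equal(calibrateEffect(base, targetPPair = 0.5)$effect, 0)
  # smaller target, strictly larger effect
  eH <- calibrateEffect(base, targetPPair = 4.5e-18, nRef = 2e4)$effect
  eM <- calibrateEffect(base, targetPPair = 9.1e-14, nRef = 2e4)$effect
  eL <- calibrateEffect(base, targetPPair = 1.6e-8, nRef = 2e4)$effect
  expect_gt(eH, eM)
  expect_gt(eM, eL)
  expect_error(calibrateEffect(base, targetPPair = 1e-300, nRef = 50),
               "unreachable")
})

test_that("regenerated data recover the calibrated significance level", {
  sp <- calibrateEffect(causalPairSpec(0.055, 0.31, pattern = "int_Dom_Dom"),
                        targetPPair = 1.6e-8, nRef = 20000)
  set.seed(45)
  pp <- replicate(30, {
    d <- simulateCausalPair(20000, sp)
    sipiPair(d$g1, d$g2, d$y)$p_pair
  })
  # median scan p within an order of magnitude of the target
  expect_lt(abs(log10(median(pp)) - log10(1.6e-8)), 1)
})

test_that("cluster layout pairs a hub with the causal partner and six nulls", {
  sp <- causalPairSpec(0.2, 0.3, pattern = "int_Dom_Dom", effect = 0.4)
  cl <- buildPart1Cluster(sp, n = 500, hub = 1L, seed = 46)
  expect_equal(nrow(cl$data), 8L)
  expect_equal(nrow(cl$pairs), 7L)
  expect_equal(cl$pairs[1, ], c("C1", "C2"))
  expect_true(all(cl$pairs[-1, 1] == "C1"))
  expect_equal(cl$pairs[-1, 2], paste0("N", 1:6))
  expect_equal(snpInfo(cl$data)$maf[3:8], c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5))
  cl2 <- buildPart1Cluster(sp, n = 500, hub = 2L, seed = 46)
  expect_true(all(cl2$pairs[-1, 1] == "C2"))
  # peripheral nulls are generated independently of the hub
  big <- buildPart1Cluster(sp, n = 2e4, seed = 47)
  g <- genotypes(big$data)
  expect_lt(ldR2(g["C1", ], g["N3", ]), 0.005)
})

test_that("the hybrid layout partitions pairs into the four documented classes", {
  ds <- buildPart2Dataset(n = 400, nullPerMaf = 100L, seed = 48)
  expect_equal(nrow(ds$data), 614L)
  info <- snpInfo(ds$data)
  expect_equal(sum(info$role == "causal"), 14L)
  expect_true(all(info$maf[info$role == "causal"] >= 0.06 - 1e-9))
  expect_true(all(info$maf[info$role == "causal"] <= 0.46 + 1e-9))
  ids <- rownames(ds$data)
  allp <- t(combn(ids, 2))
  res <- data.frame(snp1 = allp[, 1], snp2 = allp[, 2],
                    stringsAsFactors = FALSE)
  res <- classifyPairs(res, setNames(info$role, ids), ds$causalPairs)
  counts <- table(res$class)
  expect_equal(unname(counts["C-C"]), 7)
  expect_equal(unname(counts["C-N"]), 8400)
  expect_equal(unname(counts["N-N"]), 179700)
  expect_equal(unname(counts["C-C-other"]), 84)
  expect_equal(sum(counts), countPairs(614))
})
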