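test_that("evalRule reproduces the documented decisions", {
  # an observed pair: p_pair beats the criterion and both main effects
  expect_true(evalRule(5.7e-18, 2.2e-15, 0.027, criterion = 2.7e-7))
  # splits the rules: p_main1 below p_pair
  expect_true(evalRule(1e-8, criterion = 2.7e-7, rule = "1pRule"))
  expect_false(evalRule(1e-8, 1e-10, 0.5, criterion = 2.7e-7))
  # boundary: comparisons are strict
  expect_false(evalRule(2.7e-7, 1, 1, criterion = 2.7e-7))
  expect_false(evalRule(0.5, 0.5, 0.9, criterion = 0.9))
})

test_that("3pRule-significant pairs are a subset of 1pRule-significant pairs", {
  set.seed(31)
  for (i in 1:200) {
    pp <- 10^runif(1, -10, 0)
    pm <- 10^runif(2, -10, 0)
    crit <- 10^runif(1, -8, -1)
    s3 <- evalRule(pp, pm[1], pm[2], crit)
    s1 <- evalRule(pp, criterion = crit, rule = "1pRule")
    expect_true(!s3 || s1)
    # the rules agree whenever both main effects are at or above the criterion
    if (all(pm >= crit)) expect_identical(s3, s1)
  }
})

test_that("scanPairs flags all pairs and respects rule implication", {
  d <- makeNullData(n = 250, mafs = rep(c(0.2, 0.4), 5), seed = 32)
  sc <- scanPairs(d$g, y = d$y, criterion = 0.05)
  expect_equal(nrow(sc), countPairs(10))
  expect_true(all(sc$evaluable))
  expect_true(all(sc$sig_1p[sc$sig_3p]))
  # default criterion is the pairwise Bonferroni threshold
  sc2 <- scanPairs(d$g[, 1:4], y = d$y)
  expect_equal(attr(sc2, "criterion"), 0.05 / countPairs(4))
})

test_that("the main-effect prefilter skips weak pairs without changing fitted ones", {
  d <- makeNullData(n = 250, seed = 33)
  full <- scanPairs(d$g, y = d$y, criterion = 0.05)
  thr <- sort(full$p_main1)[2]
  filt <- scanPairs(d$g, y = d$y, criterion = 0.05, prefilterPmain = thr)
  skipped <- is.na(filt$p_pair)
  expect_true(any(skipped))
  both_weak <- full$p_main1 > thr & full$p_main2 > thr
  expect_identical(skipped, both_weak)
  expect_equal(filt$p_pair[!skipped], full$p_pair[!skipped])
})

test_that("per-pair complete-case handling drops only affected subjects", {
  d <- makeNullData(n = 300, seed = 34)
  gm <- d$g
  gm[1:10, 1] <- NA
  sc <- scanPairs(gm, y = d$y, criterion = 0.05)
  ref <- scanPairs(d$g[-(1:10), c(1, 2)], y = d$y[-(1:10)], criterion = 0.05)
  r12 <- sc[sc$snp1 == "rs1" & sc$snp2 == "rs2", ]
  expect_equal(r12$p_pair, ref$p_pair[1])
  # pairs not involving rs1 use all subjects
  ref34 <- scanPairs(d$g[, c(3, 4)], y = d$y, criterion = 0.05)
  r34 <- sc[sc$snp1 == "rs3" & sc$snp2 == "rs4", ]
  expect_equal(r34$p_pair, ref34$p_pair[1])
  expect_error(scanPairs(gm, y = d$y, missing = "error"), "missing")
})

test_that("bootData resamples subjects with replacement, phenotype attached", {
  d <- makeNullData(n = 400, seed = 35)
  ge <- GenotypeExperiment(d$g, phenotype = d$y)
  b1 <- bootData(ge, seed = 9)
  expect_equal(ncol(b1), 400L)
  b2 <- bootData(ge, seed = 9)
  expect_identical(genotypes(b1), genotypes(b2))
  # resampled columns keep genotype-phenotype linkage
  orig <- sub("\\..*$", "", colnames(b1))
  expect_identical(unname(phenotype(b1)), unname(phenotype(ge)[orig]))
  # expected distinct-subject fraction ~ 1 - exp(-1)
  set.seed(36)
  fr <- replicate(300, length(unique(sample.int(400, 400, TRUE))) / 400)
  expect_equal(mean(fr), 1 - exp(-1), tolerance = 0.01)
})

test_that("bootstrap selection frequencies are reproducible and monotone in tau", {
  sp <- calibrateEffect(causalPairSpec(0.3, 0.25, pattern = "int_Dom_Dom"),
                        targetPPair = 1e-9, nRef = 1200)
  set.seed(37)
  cp <- simulateCausalPair(1200, sp)
  nul <- t(genotypes(simulateNullSnps(1200, c(0.2, 0.4))))
  g <- cbind(C1 = cp$g1, C2 = cp$g2, nul)
  ge <- GenotypeExperiment(g, phenotype = cp$y)
  bs <- boot3p(ge, B = 12L, criterion = 1e-4,
               thresholds = c(0.5, 0.75, 0.9), seed = 5)
  expect_equal(nrow(bs), countPairs(4))
  expect_true(all(bs$freq >= 0 & bs$freq <= 1))
  expect_equal(bs$freq, bs$count / 12)
  # monotone: selected set shrinks as tau grows
  expect_true(all(bs$`sel_0.9` <= bs$`sel_0.75`))
  expect_true(all(bs$`sel_0.75` <= bs$`sel_0.5`))
  # a strong causal pair is selected in nearly every replicate
  cc <- bs[bs$snp1 == "C1" & bs$snp2 == "C2", ]
  expect_gte(cc$freq, 0.75)
  bs2 <- boot3p(ge, B = 12L, criterion = 1e-4,
                thresholds = c(0.5, 0.75, 0.9), seed = 5)
  expect_identical(bs$freq, bs2$freq)
})
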