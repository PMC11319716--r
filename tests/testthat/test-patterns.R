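# Independent dedup oracle: two candidate models are equivalent iff their
# fitted deviances agree (to tolerance) on several random datasets, directly
# or after swapping the SNPs. Uses stats::glm.fit, not the package's fitter.
test_that("catalog deduplication yields exactly 45 patterns, matching a glm deviance oracle", {
  cat45 <- enumeratePatterns()
  pt <- patternTable(cat45)
  expect_equal(nrow(pt), 45L)
  expect_equal(anyDuplicated(pt$pattern_id), 0L)

  # brute-force oracle over all 144 candidates
  set.seed(42)
  datasets <- lapply(1:3, function(i) {
    g1 <- sample(0:2, 120, TRUE, c(.4, .4, .2))
    g2 <- sample(0:2, 120, TRUE, c(.3, .5, .2))
    list(g1 = g1, g2 = g2, y = rbinom(120, 1, 0.5))
  })
  structures <- c("full", "snp1_int", "snp2_int", "int_only")
  codings <- codingTable()
  designFor <- function(s, c1, c2, d) {
    x1 <- applyCoding(d$g1, codings$mode[c1], codings$direction[c1])
    x2 <- applyCoding(d$g2, codings$mode[c2], codings$direction[c2])
    switch(s,
           full = cbind(1, x1, x2, x1 * x2),
           snp1_int = cbind(1, x1, x1 * x2),
           snp2_int = cbind(1, x2, x1 * x2),
           int_only = cbind(1, x1 * x2))
  }
  devSig <- function(s, c1, c2, dsets) {
    paste(vapply(dsets, function(d) {
      X <- designFor(s, c1, c2, d)
      if (qr(X)$rank < ncol(X)) return(NA_real_)
      round(suppressWarnings(
        stats::glm.fit(X, d$y, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-12))$deviance),
        4)
    }, 0), collapse = ",")
  }
  swapped <- lapply(datasets, function(d) list(g1 = d$g2, g2 = d$g1, y = d$y))
  sigs <- character(0)
  for (s in structures) for (c1 in 1:6) for (c2 in 1:6) {
    k1 <- devSig(s, c1, c2, datasets)
    k2 <- devSig(s, c1, c2, swapped)
    sigs <- c(sigs, paste(sort(c(k1, k2)), collapse = "|"))
  }
  expect_equal(length(unique(sigs)), 45L)
})

test_that("full-structure candidates differing only by coding direction share deviance", {
  set.seed(7)
  g1 <- sample(0:2, 200, TRUE, c(.4, .4, .2))
  g2 <- sample(0:2, 200, TRUE, c(.2, .5, .3))
  y <- rbinom(200, 1, 0.5)
  dev <- function(c1d, c2d) {
    x1 <- applyCoding(g1, c1d[[1]], c1d[[2]])
    x2 <- applyCoding(g2, c2d[[1]], c2d[[2]])
    suppressWarnings(stats::glm.fit(cbind(1, x1, x2, x1 * x2), y, family = stats::binomial())$deviance)
  }
  # additive reversal is affine: no new model
  base <- dev(list("dominant", "original"), list("additive", "original"))
  expect_equal(dev(list("dominant", "original"), list("additive", "reverse")),
               base, tolerance = 1e-6)
  # reversing a binary coding swaps it with the complementary mode:
  # dominant/reverse == 1 - recessive, recessive/reverse == 1 - dominant
  expect_equal(dev(list("dominant", "reverse"), list("additive", "original")),
               dev(list("recessive", "original"), list("additive", "original")),
               tolerance = 1e-6)
  expect_equal(dev(list("recessive", "reverse"), list("additive", "original")),
               base, tolerance = 1e-6)
})

test_that("catalog construction is deterministic and its structure mix is fixed", {
  a <- patternTable(enumeratePatterns())
  b <- patternTable(enumeratePatterns())
  expect_identical(a, b)
  expect_equal(as.vector(table(a$structure)[c("full", "main_int", "int_only")]),
               c(6L, 18L, 21L))
  expect_equal(sum(a$symmetric), 9L)   # 3 full + 6 int-only self-swap classes
})

test_that("pattern designs expose the documented interaction variables", {
  X <- patternDesign("int_Add_Add", c(0, 1, 2, 2), c(0, 2, 1, 2))
  expect_equal(unname(X[, ncol(X)]), c(0, 2, 2, 4))
  expect_true(all(pairVariable(sample(0:2, 50, TRUE), sample(0:2, 50, TRUE),
                               "int_Add_Add") %in% c(0, 1, 2, 4)))
  expect_true(all(pairVariable(sample(0:2, 50, TRUE), sample(0:2, 50, TRUE),
                               "int_Dom_Dom") %in% c(0, 1)))
  expect_error(patternDesign("no_such_pattern", 0:2, 0:2), "unknown pattern")
})

test_that("the catalog TSV export round-trips", {
  path <- tempfile(fileext = ".tsv")
  writeCatalog(enumeratePatterns(), path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 45L)
  expect_equal(back$pattern_id, patternTable(enumeratePatterns())$pattern_id)
})
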