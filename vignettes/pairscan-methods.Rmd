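---
title: "Pattern-based SNP-SNP interaction scanning: models, rules and simulators"
author: "pairscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based SNP-SNP interaction scanning: models, rules and simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscan)
```

## The problem

Pairwise SNP-SNP interaction scans test whether two genetic variants jointly
predict a binary trait beyond their marginal effects. The conventional test
(the "AA-Full" model, `y ~ g1 + g2 + g1:g2` with both SNPs coded additively)
assumes one specific interaction shape and misses interactions expressed
under dominant or recessive inheritance or acting on the major allele, which
costs power. Conversely, flexible pattern searches create a subtler problem:
significant pairs tend to arrive in *clusters* sharing a hub SNP, and many
cluster members are false positives driven by the hub's main effect rather
than by a real joint signal. This package implements both halves of that
story: the flexible pattern scan, and the diagnostics and significance rules
that keep its false positivity under control.

## The pattern catalog

For each pair the scan considers logistic models built from three factors:

* **structure** — full (`~ x1 + x2 + x1:x2`), one SNP's main effect plus the
  interaction (two variants), or interaction-only (`~ x1:x2`);
* **inheritance mode** — additive (0,1,2), dominant (0,1,1), recessive
  (0,0,1) coding of the minor-allele count;
* **coding direction** — original (minor allele) or reverse (the same mode
  applied to the major allele, i.e. to `2 - g`).

This yields 4 x 6 x 6 = 144 candidates, but many are statistically
equivalent. Reversal of an additive coding is affine (`2 - g`), and
reversing a dominant coding gives the complement of the recessive coding
(`1 - Rec`) and vice versa, so within some structures different labels span
the same design space. `enumeratePatterns()` removes duplicates by an
explicit oracle: two candidates are equivalent when their design matrices
span the same column space on the generic 9-row table of all `(g1, g2)`
combinations, either directly or after swapping the two SNPs (a pair is
unordered, so a model and its mirror image describe the same hypothesis).
Deduplication leaves exactly **45** pattern classes: 6 full, 18
main-plus-interaction and 21 interaction-only. The dedup is recomputed at
catalog construction and the count is asserted; the suite cross-checks it
with an independent deviance-identity oracle.

Asymmetric classes are fitted in both orientations at scan time — 81 ordered
designs per pair — and each class scores its better orientation. This is
what makes `sipiPair(g1, g2, y)` exactly symmetric in its arguments, which
we treat as non-negotiable for an unordered pair. A consequence worth
knowing: selection is slightly deeper than in an order-dependent 45-design
scan, and the null distribution of the selected interaction p-value sits at
the lower edge of its reference band (see "What the generators emulate").

## Fitting and selection

Every design is a logistic regression fitted by IRLS with a fixed contract:
convergence when the relative log-likelihood change falls below `1e-8`
(at most 50 iterations); (quasi-)separation flagged when any coefficient
exceeds 15 on the log-odds scale; rank-deficient designs flagged degenerate.
Degenerate, separated and non-converged fits are excluded from model
competition rather than penalised — a diverged likelihood makes BIC
meaningless. Fits that stop inside the bound compete exactly as they would
in a standard `glm`-based scan; we deliberately did not add a stricter
divergence detector, because excluding those near-flat fits measurably
shifts the null summary statistics away from what a `glm`-based scan
produces.

Because every covariate of every pattern is constant within the 9 joint
genotype cells, the likelihood depends on the data only through the per-cell
case/control counts. The scan therefore fits the binomial-aggregated 9-row
representation — identical maximum likelihood, log-likelihood and Wald
standard errors — at a cost independent of the subject count. A full-data
fitter (`fitLogistic()`) with the same contract is exported for arbitrary
designs, and the test suite asserts agreement with `stats::glm` to numerical
precision on both routes.

Selection uses the Bayesian information criterion,
`BIC = k log(n) - 2 logL` with `k` counting all coefficients including the
intercept. The best pattern is the smallest BIC among eligible fits, ties
broken by catalog order (full structures first, then main-plus-interaction,
then interaction-only) — deterministic, and ties are measure-zero. Two
p-values summarise a pair:

* `p_pair` — the Wald p-value of the interaction term in the BIC-best
  pattern (for interaction-only structures, the sole covariate). A
  likelihood-ratio alternative is available via `pMethod = "lrt"`; Wald is
  the default because that is what pattern-scan outputs conventionally
  report. The two agree to within half an order of magnitude in practice.
* `p_main` — per SNP, the smallest Wald p across the three inheritance
  modes in original direction only; reversal is a relabelling that leaves a
  single-covariate logistic p-value unchanged, so testing it would double
  the count without adding information.

## Significance rules

With a criterion `c` (typically the pairwise Bonferroni threshold,
`0.05 / countPairs(m)`):

* **1pRule**: significant iff `p_pair < c`;
* **3pRule**: additionally `p_pair < p_main(SNP1)` and
  `p_pair < p_main(SNP2)`.

All comparisons are strict, so the two rules disagree only when a main
effect is itself below the criterion — exactly the hub-SNP situation that
generates false-positive clusters. The subset relation
`significant(3pRule) ⊆ significant(1pRule)` holds by construction and is
asserted as a property test; every false-positivity metric under 3pRule is
therefore bounded by its 1pRule counterpart.

`boot3p()` adds bootstrap stability selection: `B` resamples of subjects
with replacement (same sample size; phenotype rows travel with genotype
rows), a complete re-scan per replicate — main effects are recomputed inside
each replicate, since the rule is a per-dataset criterion — and per-pair
selection frequencies thresholded at `tau` in {0.75, 0.80, 0.85, 0.90} by
default. Per-replicate seeds derive from one root seed, so results are
independent of execution order.

## What the synthetic generators emulate

`simulateNullSnps()` draws independent multinomial genotypes under
Hardy-Weinberg equilibrium at MAFs {0.05, 0.1, 0.2, 0.3, 0.4, 0.5} — the
null-SNP panel of the study design (100 SNPs per MAF, n = 20,000 for the
hybrid layout).

`simulateCausalPair()` generates an interaction-only signal:
`logit P(y=1) = a + b z`, where `z` is the interaction variable of a chosen
interaction-only pattern. Interaction-only is the default generating family
because it is the model class most often selected for significant pairs in
practice. The coefficients behind the published simulations are not printed,
so `calibrateEffect()` replaces them by construction: it solves for `b` such
that the median interaction p-value at a reference sample size equals a
stated target (for the first simulation set: 4.5e-18 / 9.1e-14 / 1.6e-8 at
n = 20,000). The default method is analytic — the Wald non-centrality of the
generating model under the 9-cell HWE distribution, with the intercept
re-solved at each `b` to hold prevalence — and is monotone in `|b|`; a
Monte-Carlo bisection on the scan's median `p_pair` is available for
generating models outside the analytic family. Self-consistency (regenerate
and rescan, median within an order of magnitude of the target) is asserted
in the suite. Targets for the simulation sets whose values are not printed
are package defaults spanning the stated high-significance range down to
6.7e-5.

The outcome prevalence defaults to 0.5 (the study conditions never state a
case fraction; null p-value distributions are asymptotically prevalence-free
and 0.5 maximises information at fixed n). It is configurable per spec.

Layout builders assemble the two study designs. `buildPart1Cluster()`: one
causal pair plus six peripheral null SNPs at the MAF grid; the evaluated
pairs are the causal pair and hub-vs-null pairs. `buildPart2Dataset()`: 614
SNPs — 7 causal pairs (MAFs 0.06-0.46, targets 5.7e-18 to 3.4e-9) plus 600
null SNPs — with one shared outcome whose linear predictor sums all seven
calibrated interaction terms, the intercept solved on the realised sample so
prevalence hits 0.5. The pair classes partition the 188,191 pairs into
7 / 8,400 / 179,700 / 84 (C-C / C-N / N-N / C-C-other).

What the generators do **not** emulate: linkage disequilibrium (all SNPs are
drawn independently; the cluster effect reproduced here is the
correlation-induced one, not an LD artefact — matching the observation that
LD is not the cause), covariates, genotyping error or missingness patterns,
and quantitative traits. Passing tests therefore demonstrate the method's
behaviour under clean HWE sampling with interaction-only causal signals, not
robustness to real-data artefacts.

## Metrics

`computeRates()` pools flagged results into the study's positivity metrics:
TIR/FIR (proportion of significant calls for causal/null pairs across
simulation replicates; FIR pools the six null pairs of a cluster over runs,
which equals per-pair averaging when reported per condition) and TPR/FPR for
the single-dataset hybrid layout. `fprCluster()` restricts FPR to the null
pairs sharing a hub SNP, with a per-MAF breakdown; `clusterCorrelations()`
correlates the causal pair's selected interaction variable with each
significant null pair's (Pearson; the Phi coefficient when both are binary,
which is the same formula). `ldR2()` is the squared dosage correlation —
composite LD, appropriate for unphased independent simulations — with 0.8 as
the conventional strong-LD cut. `ppairPmainCorrelation()` rank-correlates
`p_pair` with the stronger of the two `p_main`s ("most significant composite
SNP" = the smaller p_main, ties by SNP order).

## Numerical choices and problem sizes

The simulation criterion default is `1e-4` (the empirical cut below which
almost no null-null pair falls); the hybrid criterion default is the
pairwise Bonferroni threshold `2.7e-7`. The two printed criteria are not
identical in the source material, so the criterion is everywhere a
parameter, never hard-coded. Reference summaries this package reproduces
from its own simulations, at the scales its tests use (600 null SNPs at
n = 20,000 for main effects, three seeds; ~12,000-18,000 null pairs at
n = 20,000 for the scan): mean/median best-mode `p_main` about 0.33/0.29;
mean/median null `p_pair` about 0.11-0.13/0.06-0.07; about 99.9% of null
pairs at or above `1e-4`; no null pair below `2.7e-7`. The cluster
simulation drivers default to reduced grids (tens of runs, n in the low
thousands) and scale up by argument; trend properties (FIR falling in
peripheral MAF, rising in hub significance; TIR rising in n) are asserted as
directions, not point values, at those reduced scales.

Degenerate inputs are contracts, not surprises: constant genotype columns
error in `snpMain()`/`sipiPair()`; codings degenerate on the data (e.g.
recessive with no minor-allele homozygote) are skipped per mode or excluded
per design; missing genotypes follow a per-pair complete-case policy
(configurable to reject) — the sources are silent on missingness, and
complete-case is standard GLM practice.

## Known limitations

* The real consortium genotypes behind the published tables are restricted;
  their exact table values are out of reach by design. This package
  regenerates the fully simulation-defined quantities and the layout/analytic
  constants, and emulates the rest.
* The 45-pattern catalog is fixed by the column-space + swap-equivalence
  oracle. It agrees with the published catalog in size and factor structure;
  per-pattern labels may order differently from other implementations.
* Wald p-values in near-separated fits exhibit the Hauck-Donner effect
  (p near 1); such fits rarely win selection and bias `p_pair` upward
  (conservatively) when they do.
* Bootstrap scans are embarrassingly parallel in principle; this
  implementation runs them serially with order-invariant seeding.
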