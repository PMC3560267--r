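---
title: "Aggregated MDR: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated MDR: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `amdr` computes, the assumptions behind each
stage, and the design decisions taken where the method description leaves
room.  It is the package's reference for *why* the code is the way it is;
the README shows *how* to run it.

## 1. The predisposing risk factor

For a set of $k$ biallelic SNPs coded $0/1/2$, the $3^k$ genotype
combinations are the cells $C_{ij}$; $X_{ij}$ and $Y_{ij}$ count cases and
controls in cell $j$ of combination $i$.  The naive Bayes threshold

$$p_0 = \frac{\sum_j X_{ij}}{\sum_j X_{ij} + \sum_j Y_{ij}}$$

is the overall case fraction (identical for every combination on a fixed
dataset).  A cell is **high risk** when $X_{ij}/(X_{ij}+Y_{ij}) > p_0$,
strictly; ties and empty cells ($0/0$, defined as $0$) are low risk.  The
empty-cell rule matters twice: it keeps the indicator sums equal to a sum
over observed subjects, and it makes risk scoring of genotype combinations
never seen during analysis well defined (they contribute nothing).
Summing cells within risk strata yields the 2×2 predisposing table
$(n_{11}, n_{12}, n_{21}, n_{22})$ with expected counts
$e_{st} = n_{s+} n_{+t} / N$.  A table whose high- or low-risk stratum is
empty is *degenerate*: its statistics are reported as `NA` and the
interaction is excluded from FDR ranking.

Assumptions: unrelated subjects, a binary phenotype with both classes
present, complete genotypes after load (missingness is a load-time policy:
fail, or drop subjects with a logged count).

## 2. Raw statistics and their calibration

The raw odds ratio, relative risk and chi-square of the predisposing table
are *not* nominally distributed under the null: the high-risk stratum is
selected from the same data, so even for non-interacting pairs the raw OR
concentrates well above 1 (the package's tests assert a null median
around 2).  The calibration divides each raw statistic $x$ by
$F_0^{-1}(F(x))$:

* $F_0$, the null CDF, is estimated from $B$ phenotype permutations
  (each subject's SNP vector kept intact; threshold and cell
  classification recomputed per permutation — a fixed-partition null was
  evaluated and discarded, as it inherits the selection bias and its
  type-I error is an order of magnitude too high);
* $F$, the alternative CDF, is estimated from $B_j$ jackknife subsamples
  (a fraction $f$ of subjects without replacement, SNP–phenotype vectors
  kept intact, both classes enforced with up to 100 redraws).

Both CDFs use the order-statistic estimator
$\hat F(x) = B^{-1}\sum_i I\{x_i \le x\}$ and its inverse
$\hat F^{-1}(p) = \inf\{x : \hat F(x) \ge p\}$ (implemented as the
$\lceil pB \rceil$-th order statistic with a $10^{-9}$ guard against
floating-point round-up).  Under the null $F \approx F_0$ and the
calibrated statistic centres at 1.  When $F(x)$ falls below every null
sample the denominator clamps to the smallest positive null sample.

**Zero cells.** OR and RR receive the Haldane–Anscombe $+0.5$ correction
in all four table cells whenever any cell is zero, keeping every resampled
statistic finite so the empirical CDFs are well defined.  Chi-square uses
the raw counts, with any term of expected count 0 contributing 0.

**p-values.** The permutation p-value is the strict upper-tail fraction
$p = B^{-1}\#\{i : x < x_i\}$ computed *on the raw-statistic scale*.
Because the calibration holds one fixed $F$ and $F_0$, it is a monotone
transform wherever it is defined, and the raw-scale count equals the
calibrated-scale count there.  Computing the reference values on the
calibrated scale directly is numerically treacherous: permuted statistics
fall below the support of $F$, hit the denominator clamp, and a small
permuted chi-square divided by a near-zero clamp can exceed the observed
calibrated statistic by orders of magnitude.  (A fully nested
re-calibration per permutation would avoid this at $O(B^2 B_j)$ cost per
pair; it is not implemented.)  An add-one variant
$(1+\#)/(B+1)$ is available behind `conservative = TRUE`.

**Confidence intervals.** The 95% CI is the 2.5th–97.5th order-statistic
percentile interval of the calibrated jackknife resamples, after centring
them on the observed calibrated statistic and inflating the deviations by
$\sqrt{f/(1-f)}$ (3 for the default $f = 0.9$).  This is the standard
$m$-out-of-$n$ subsampling scale-up: a 90% subsample explores only about a
third of the full sampling spread, and the unscaled percentile band covers
1 under the null far below nominal rate, contradicting the method's own
rationale that null intervals should cross 1.  The acceptance suite
verifies the calibrated medians and the coverage on permuted-phenotype
data.  `ci_source = "permutation"` switches the resample set (scale 1).

**Multiplicity.** Benjamini–Hochberg across all $\binom{M}{k}$ tests,
separately per statistic, via `p.adjust`.

## 3. Risk aggregation

With significance threshold $\alpha$, subject $n$ scores

$$R(k,n) = \sum_i I\{p_i < \alpha\} \sum_j I\{n \in C_{ij}\}
           I\{X_{ij}/(X_{ij}+Y_{ij}) > p_0\},$$

an integer bounded by the number of significant interactions.  The
inclusion inequality is strict, as is the cell-risk rule.  $\hat\alpha$
maximises the AUC of the score over $[0, 0.05]$; the candidate grid
contains one boundary just past each distinct observed p-value below 0.05
(midpoints to the next one), so every realisable set of admitted
interactions is tried — a continuous scan cannot produce any other score
vector.  Ties go to the smallest candidate: fewer, stronger interactions
are preferred to diluting the score.  AUC uses the rank (concordance)
formula with 0.5 credit for ties; the classification cutoff scans all
midpoints between adjacent distinct scores (plus one boundary either side)
and ties go to the lower cutoff.  Scores, $\hat\alpha$, AUC and accuracy
are evaluated in-sample, mirroring the method's intended use on a single
study; no holdout is performed.

## 4. The epistasis network

Pairwise ($k = 2$) interactions passing the significance rule (default
FDR < 0.05; unadjusted p available) become edges weighted by pOR.  With a
SNP→gene map the graph collapses to gene level, keeping parallel edges
with their SNP annotations; two SNPs of one gene yield a flagged
self-edge.  Exports: lossless edge TSV, Graphviz DOT (pen width a
monotone, rank-based function of pOR), GraphML via igraph.

## 5. Original MDR reference

The comparison implementation uses stratified 10-fold cross-validation
(fold assignment seeded and canonicalised by sorted subject id, so results
are row-order invariant).  Cells are labelled high/low against the
training-fold case fraction; the per-order best model follows the classic
convention — maximal cross-validation consistency (CVC = number of folds
whose training-accuracy winner it is), ties by mean testing accuracy, then
lexicographic order.  Selection by testing accuracy alone was tried first
and identifies a planted moderate-effect pair markedly less often; CVC
selection is both the historical rule and the better-performing one.  The
permutation test re-runs the *entire* search (including CVC selection) on
each of $B$ phenotype reshuffles and compares selected-model testing
accuracies, which charges the observed statistic and the null the same
selection bounty.

## 6. The synthetic-data generator

Five SNPs are drawn independently under Hardy–Weinberg equilibrium
($(1-q)^2, 2q(1-q), q^2$; code 0 = common homozygote).  Disease status
comes from two-locus penetrance tables: two checkerboard models (pure
epistasis, no marginal effects, MAF 0.5) and two noisy-interaction models
with marginal locus effects (MAF 0.25).  Three architectures:

* **single pair** — $P(D\,{=}\,1) = p_{12}(g_1, g_2)$, loci 3–5 inert;
* **genetic heterogeneity** — each subject carries a latent source $C$;
  affected subjects split $\gamma_1 : \gamma_2$ between the loci-1×2 and
  loci-4×5 routes.  The split is enforced on the *case sample* (per-source
  quotas during rejection sampling), the design of the classic
  heterogeneity simulations this follows; the marginal susceptibility
  $\gamma_1 p_{12} + \gamma_2 p_{45}$ is what `susceptibility()` reports;
* **additive** — $p_{12} + p_{45} - p_{12}p_{45}$, the union of two
  independent disease routes.

Rejection sampling fills $n/2$ cases and $n/2$ controls (draw cap $10^7$,
then an error naming unattainable penetrances).  The generator emulates
balanced retrospective sampling with linkage equilibrium and complete
genotypes; it does **not** emulate linkage disequilibrium, covariates,
genotyping error, missingness or population structure — passing tests
bound what the method does under the idealised architectures, not on real
cohorts.

The power harness declares a calibrated statistic significant at
FDR-adjusted $p < 0.05$ (the conservative reading consistent with the
method's reported type-I behaviour; unadjusted mode is available), and
original MDR significant when the causal pair is the selected model *and*
its permutation test rejects.  Type-I error is measured on pairs of loci
that are entirely outside the susceptibility function: in the MAF-0.25
models the causal loci carry real marginal effects, so pairs mixing one
causal and one inert locus contain genuine main-effect association and
would conflate main-effect detection with false positives
(`null_pairs = "all-non-causal"` restores the broader reading).

## 7. Problem sizes, seeds and runtime

Defaults: $B = 1000$ permutations, $B_j = 200$ jackknife draws,
$f = 0.9$, 10 CV folds, 200 MDR permutations inside the harness, 100
replicates per power estimate — small enough that the full simulation
study runs in minutes on one CPU, large enough that a binomial standard
error on a power estimate is at most 0.05.  All randomness flows from one
master seed through named substreams (`derive_seed(seed, label, index)`),
so changing $B$ never perturbs the simulation draws, reruns are
bit-identical, and subject order never affects any seeded draw (subjects
are canonicalised by id first).  The acceptance script reproduces the
published power table entries at these sizes; the test suite runs the same
harness plus a 200-replicate null-calibration study at $N = 200$ and exact
brute-force oracle comparisons at $N = 28$, $B = 50$.

## 8. Known limitations

* p-values have resolution $1/B$; FDR-level decisions at $B = 1000$ and
  10 tests hinge on $p < 0.005$, so $B$ should grow with $M$.
* The calibrated pOR's permutation test is, in our harness, the least
  powerful of the three statistics under the MAF-0.25 architecture;
  analyses of that kind should prefer pChi.
* One interaction order $k$ per score; mixing orders is out of scope.
* Exhaustive enumeration is $O(\binom{M}{k} 3^k (B + B_j))$; the package
  targets candidate-gene panels, not GWAS-scale scans.
* In-sample AUC and accuracy are optimistically biased; external
  validation is the user's responsibility.
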