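---
title: "Simulating and benchmarking genomic prediction in a four-way outbred cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking genomic prediction in a four-way outbred cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlgp)
```

## The population and what the simulator emulates

`qtlgp` works with the pseudo-F1 progeny of two heterozygous parents. At a
fully informative marker (abxcd segregation) the maternal parent carries
alleles `a/b`, the paternal parent `c/d`, and every offspring's genotype
class — `ac`, `ad`, `bc` or `bd` — reveals both transmitted haplotypes
unambiguously. The simulator emulates a dense consensus map for such a
cross: by default 19 chromosomes carrying 3,961 fully informative markers
with no missing data, scored on 188 offspring.

Meiosis is simulated as a two-state Markov chain per parental chromosome:
the maternal allele sequence switches between `a` and `b` with probability
`haldane_r(d)` between markers `d` cM apart, independently of the paternal
`c/d` sequence, and chromosomes are independent. We use Haldane's map
function (no interference) throughout — for progeny simulation *and* for
genotype-probability interpolation — because it makes the two-point
formulas exact for a Markov model of meiosis; the chain and the bridge
formula are then mutually consistent by construction.

Free choices the data do not pin down, and our defaults:

* **Marker spacing**: equidistant on each chromosome (an option for
  uniform-random placement exists). Spacing details do not affect any
  conclusion tested here.
* **Chromosome length**: 75 cM per chromosome, a typical per-chromosome
  length for a grapevine-scale consensus map of ~1,400 cM total.
* **Physical positions**: strictly increasing cumulative gamma increments
  scaled to 22 Mb per chromosome; only monotonicity matters (the loess
  cM↔bp conversion must be exercisable), not the local rate pattern.
* **Seeding**: every stochastic operation takes one seed that fully
  determines its output; replicate *i* of any study uses `base_seed + i`.

What the generator does **not** emulate: partially informative segregation
types (abxab, abxaa, ...), missing or erroneous genotype calls, crossover
interference, segregation distortion, and the LD structure of a real
GBS-derived map (our LD decays smoothly with cM distance; real maps have
block structure). Tests that pass on these simulations therefore validate
the *methods* under a clean Mendelian model, not their behavior under
genotyping artefacts.

## Design-matrix encoding

Each marker contributes eight predictor columns: four additive columns
counting the parental alleles (`A_a + A_b = A_c + A_d = 1` per offspring,
so the block row-sums to 2) and the four genotype-class indicators as a
dominance block (row-sum 1), giving `p = 8m` columns — 31,688 for 3,961
markers. The text naming this encoding fixes only the block structure and
`p = 8m`; we chose allele counts for the additive block because every
parental allelic effect stays explicitly representable. The eight columns
of one marker have rank 4; this deliberate redundancy is absorbed by the
penalized fits, and constant columns are kept (with zero coefficients)
so column indexing never shifts.

## Trait simulation and the heritability target

Traits follow `Y = XB + E` with `B ~ MN(0, I, V_B)` supported on the
additive rows of `s` QTL markers (all dominance effects zero) and
`E ~ MN(0, I, V_E)`. Default parameters mirror the benchmark's first
simulation set — σ²_B = 0.1 per trait, ρ_B = 0.8, ρ_E = 0, s ∈ {2, 50},
h² ∈ {0.1, 0.2, 0.4, 0.8} — and the second set (s ∈ {20, 200}, σ²_B = 1,
ρ_B = 0.5, h² = 0.1/0.5) runs through the same code path. Under the
`"same"` distribution both traits share one QTL set; under `"diff"` the
sets are disjoint, so the genetic correlation is ρ_B or 0 respectively.

The error variance is *deduced* rather than fixed: σ²_E =
var(XB)·(1−h²)/h², computed per replicate and per trait from the
**realized** sample variance of the genetic values. The alternative —
deducing from the expected variance `4s·σ²_B·E[var(X_j)]` — would let the
realized heritability drift with the luck of the effect draw; the
realized-variance rule keeps every replicate centred on its target, which
is what the recovery tests check (mean realized h² within Monte-Carlo
error of the target). Effects and errors are drawn through a symmetric
matrix square root of the covariance, which tolerates the boundary cases
(zero variance, |ρ| = 1) where a Cholesky factor does not exist.

## Interval mapping

Because the data are complete and fully informative, the genotype
probability at an interior grid position reduces to the two-point Markov
bridge: with flanking recombination fractions `r_L`, `r_R` and marker
interval fraction `r_LR`, the probability of matching two concordant
flanks is `(1−r_L)(1−r_R)/(1−r_LR)`, and `(1−r_L)r_R/r_LR` of matching a
discordant left flank; parental chromosomes multiply. At markers the
probabilities are exact indicators. The default grid step is 0.1 cM.

The Haley–Knott scan regresses the trait on the class probabilities.
Since the four probabilities sum to one, the model has three informative
degrees of freedom; we use the equivalent basis `{1, pA, pC, pA·pC}`
(maternal and paternal "first allele" probabilities and their product),
which spans the same space and keeps the RSS — and hence the LOD
`(n/2)·log10(RSS0/RSS1)` — invariant. A perfect fit is capped at LOD 300
with a warning; a zero-variance trait scans flat at LOD 0.

Thresholds come from permutations of the trait against fixed genotype
rows: 1,000 permutations at 5% FWER for detection, 10 inside
cross-validation where the threshold is only a tuning parameter.

Three stepwise-MIM choices deserve note:

* **Penalty.** The per-QTL penalty on the penalized LOD is the genome-wide
  single-scan permutation threshold. A two-dimensional permutation scan
  could refine this, but with QTL×QTL interactions excluded the
  main-effect penalty is the quantity that matters; the simplification
  changes MIM's sparsity only marginally.
* **Restarts.** Plain stepwise search is deterministic, so "replicates to
  overcome instability" are implemented as seeded random tie-breaking
  among candidates within 1e-8 of the best penalized LOD; the best model
  across restarts is returned.
* **Refinement.** After selection, positions are refined by
  coordinate-wise re-scan (each QTL re-placed with the others fixed, up to
  10 sweeps), implemented exactly by Frisch–Waugh residualization.

QTL-based prediction regresses the training trait on the stacked class
probabilities at the model positions by OLS (pivoting solve; aliased
columns get zero weight) and applies the coefficients to the test-set
probabilities; an empty model predicts the training mean.

## Penalized regression

Ridge, LASSO and elastic net are fitted by coordinate descent through
glmnet; the multivariate variants use the multi-response Gaussian family,
whose row-wise group penalty (L2 norm of each predictor's effect vector
across traits) is exactly the joint-selection penalty of the multi-task
elastic net. The package contract is the *objective*, not the algorithm;
the tests pin the objective down by closed-form ridge solves, KKT
subgradient checks for LASSO, and the α-limit equivalences EN(0) ≡ ridge,
EN(1) ≡ LASSO.

Tuning follows the benchmark protocol: mean-squared-error k-fold
cross-validation on the training data only, with the fold assignment
shared across every α value, method and trait; for the elastic net, 20
equispaced α values each with a 500-value λ path (both reducible through
`control` arguments when embedded in larger designs). Ties in the CV
error resolve to the largest (sparsest) λ, which is the first minimum on
the decreasing path. Predictors are standardized internally by their
population SD and coefficients returned on the original scale; one
convention to be aware of is that the solver also works on the
unit-variance response scale, so the reported λ values correspond to an
effective ridge penalty of λ/sd(y) in raw units — immaterial for tuned
fits, but visible in closed-form comparisons.

## Robust marker selection

**Stability selection** refits the LASSO path on repeated half-samples
(⌊n/2⌋ without replacement; 100 subsamples by default, a conventional
count — the protocol text does not fix one) and scores each predictor by
the fraction of half-samples where it is nonzero *at any λ of the grid*,
per the procedure's definition; thresholds 0.6 (univariate) and 0.7
(multivariate) are the defaults. The multivariate variant uses the group
nonzero indicator from the multi-response path.

**Marginal FDR** is estimated along a LASSO or EN path from the marginal
null: a null predictor (standardized, `x'x = n`) enters the model when its
inner product with the residual exceeds the effective L1 threshold αλ, so
the expected false-discovery count at λ is `2p·Φ(−√n·αλ/σ̂)`, with σ̂
estimated from the residuals at that λ (RSS/(n−df)). The estimate is
clamped to [0, 1], defined as 0 for empty selections, and matches the
orthogonal-design closed form exactly. Selection at a level (10% default)
takes the smallest λ still controlled — the largest controlled model. The
estimator is univariate only; no multivariate analogue is provided.

## Evaluation

Nested cross-validation separates tuning from assessment: outer `k1 = 5`
folds estimate the metrics, inner `k2 = 5` folds (or the 10-permutation
threshold, for interval mapping) tune on the outer-training data only,
and the seeded outer partition is reused across methods and traits so
comparisons share splits. Metrics: Pearson and Spearman correlations,
RMSPE, Nash–Sutcliffe-type model efficiency, and bias/slope t-tests from
regressing observations on predictions. Constant predictions are reported
as correlation 0 with a degeneracy flag rather than NA, so cell means
never silently drop folds. For equal-heritability simulations the
averaging runs over traits × replicates × folds; otherwise traits are kept
apart.

ROC scoring uses the ±2 cM true-positive window: TPR is the fraction of
simulated QTLs with a selected marker within 2 cM, FPR the number of
selected markers outside every window divided by the count of markers
outside all windows. Because that denominator scales with map density,
FPR values are only comparable across maps of similar density — a point
that matters when scaling simulations down. The partial AUC integrates
TPR over FPR ∈ [0, 0.1] by trapezoid; observed curves are anchored at
(0, 0) when their smallest FPR is positive and extended horizontally to
0.1 when they end early, so a perfect step curve scores 0.1 and the
diagonal 0.005.

## Consensus QTL intervals

LD is squared Pearson correlation of a 0/1/2 dose recoding (count of `a`
plus `c` alleles), computed within chromosomes; the expansion threshold is
the 95% quantile of all within-chromosome pairwise values. Expansion is a
*single pass* — proxies of proxies are not pulled in — to avoid
chromosome-wide percolation on dense maps. A marker is highly reliable
when ≥5 distinct method labels select it (post expansion) or when both
EN.mFDR and MIM do; anchors grow ±3 cM windows that merge when they
overlap, are clipped at chromosome ends, and are converted to physical
coordinates by a span-0.3 loess of bp on cM with an isotonic correction
(chromosomes with <5 markers fall back to linear interpolation, with a
warning). Variance explained per trait is the adjusted R² of OLS on the
anchors' additive codings, with aliased columns dropped by the pivoting
solve.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script scale the study down to run
quickly on one CPU, as the package's own choice of desk-scale study
conditions:

* encoding and simulator-recovery checks run at full size (19
  chromosomes, 3,961 markers, 188 offspring; 30 replicates for the
  recovery means, 100 for the effect-variance mean);
* the method × architecture × heritability prediction grid runs on a 19 ×
  8-marker map with 188 offspring, 3 replicates per cell, reduced tuning
  grids (3 α values, 25-λ paths, 10 permutations) and SIM as the
  interval-mapping representative — the quantity reported is the *best*
  cell mean, which is insensitive to these reductions because the best
  cell (few major QTLs, h² = 0.8) is easy for several methods at once;
* the false-positive-rate check for the robust selectors runs on a 19 ×
  100-marker map, because the FPR denominator scales with map density and
  only a dense map reproduces the regime in which the ±2 cM window
  contains a QTL's LD neighbours.

## Known limitations

* Only fully informative abxcd markers are supported; the genotype
  probability machinery deliberately omits the HMM needed for partially
  informative or missing data.
* The MIM penalty simplification above makes MIM slightly more liberal
  than a two-dimensional-scan calibration would.
* mFDR control is univariate; multivariate mFDR is out of scope.
* Dominance and epistatic QTL effects are not simulated (dominance
  *columns* exist in the design, but simulated effects are additive).
* Experimental-data preprocessing (mixed-model BLUP extraction from raw
  phenotypes) is out of scope: the package consumes genotypic values
  directly, and the broad-sense heritability helper implements the
  balanced-design formula given variance components.
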