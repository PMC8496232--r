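# qtlgp

Genomic prediction and QTL detection in four-way outbred crosses.

`qtlgp` is a simulation and benchmarking toolkit for the pseudo-F1 progeny
of two heterozygous parents — the cross design common in grapevine, forest
trees and other outcrossing perennials. At every fully informative marker
(abxcd segregation) each offspring carries one of four genotype classes
`ac`, `ad`, `bc`, `bd`, the pair of transmitted parental haplotypes. The
package simulates such populations and correlated quantitative traits on
top of them, fits the main families of genomic-prediction and QTL-detection
methods, and evaluates both prediction and marker selection under a
controlled truth.

## The model

Traits are simulated under the multi-trait linear model

```
Y = X B + E,    B ~ MN(0, I, V_B),    E ~ MN(0, I, V_E)
```

where `X` (n × 8m) encodes each of the `m` markers as four additive allele
counts (`a`, `b`, `c`, `d`) plus four genotype-class indicators
(dominance), `B` carries nonzero rows only at the additive columns of the
`s` QTL markers, and `V_B` is built from the per-trait genetic variance
σ²\_B and the genetic correlation ρ\_B. The error variance is *deduced*
per trait from the realized genetic variance so that each trait hits its
target narrow-sense heritability: σ²\_E = var(XB)·(1 − h²)/h².

Fitted methods:

* **Interval mapping** — simple (SIM) and multiple (MIM) interval mapping
  by Haley–Knott regression on genotype-class probabilities, computed every
  0.1 cM by the Haldane Markov bridge; genome-wide LOD thresholds by
  permutation (FWER 5%, 1000 permutations); stepwise multi-QTL search with
  a per-QTL penalized-LOD penalty; LOD-1 support intervals.
* **Penalized regression** — ridge (RR), LASSO and elastic net (EN), plus
  their multi-response counterparts (MTV\_RR, MTV\_LASSO, MTV\_EN) whose
  row-wise group penalty selects a predictor jointly across traits; tuned
  by cross-validation (for EN, 20 mixing values × 500-value λ paths).
* **Robust selection** — stability selection over half-samples
  (probability thresholds 0.6/0.7) and marginal false-discovery-rate
  control along the path (mFDR ≤ 10%).
* **Evaluation** — nested 5×5 cross-validation with shared fold
  partitions; Pearson/Spearman correlations, RMSPE, model efficiency and
  bias/slope tests; ROC curves with a ±2 cM true-positive window and
  partial AUC on FPR ∈ [0, 0.1].
* **Consensus QTLs** — LD expansion at the 95%-quantile r² threshold,
  "highly reliable" markers (≥5 methods, or MIM ∧ EN.mFDR), ±3 cM merged
  intervals with loess-based cM↔bp conversion, and adjusted-R² variance
  explained.

## A worked example

```r
library(qtlgp)

map  <- sim_genetic_map(n_chromosomes = 3, markers_per_chromosome = 20, seed = 1)
geno <- sim_cross_genotypes(map, n_offspring = 120, seed = 2)
X    <- encode_design(geno, map)
dim(X)
#> [1] 120 480

panel <- sim_trait_study(X, map, s = 2, h2 = 0.8, seed = 3)
panel
#> <qtlgp_traits> 120 offspring x 2 traits; 2/2 QTLs/trait; realized h2: 0.832, 0.758

# interval mapping: scan, permutation threshold, peaks
pr  <- calc_genoprob(geno, map, step_cM = 0.5)
sc  <- scan_sim(pr, panel$Y[, 1])
thr <- permutation_threshold(pr, panel$Y[, 1], n_perm = 200, seed = 4)
find_peaks(sc, thr)
#> # A tibble: 2 x 4
#>   chrom   pos marker   lod
#>   <chr> <dbl> <chr>  <dbl>
#> 1 chr01  13.5 <NA>    12.1
#> 2 chr03  66   <NA>    24.9

# penalized prediction with cross-validated tuning
fit <- tune_penalized(X, panel$Y[, 1], "LASSO", seed = 5)
cor(predict(fit, X)[, 1], panel$G[, 1])
#> [1] 0.993
```

The two scan peaks are pseudomarker grid positions (hence `marker = NA`)
within ~2.5 cM of the two simulated QTLs at 15.8 cM on chr01 and 67.1 cM on
chr03 (the truth is in `panel$qtl_markers`); the tuned LASSO's predictions
correlate at 0.99 with the true genetic values — the "prediction accuracy"
used throughout the package.

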