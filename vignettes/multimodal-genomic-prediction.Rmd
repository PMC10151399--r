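---
title: "Methods: multimodal genomic prediction for breeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal genomic prediction for breeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models implemented in `mmgp`, the
design decisions taken where a choice was genuinely open, the numerical
conventions, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## The problem

Genomic prediction trains a model on lines with both genotypes and phenotypes
to predict lines (or whole years/environments) that have not been phenotyped.
`mmgp` targets wheat trials with three input types: genome-wide SNP markers,
the trial year (or environment regime), and NDVI canopy reflectance measured
from the air at four vegetative and two grain-filling timepoints. Two
validation schemes matter to a breeder and behave very differently:
five-fold cross-validation partitioning *lines* (all records of a line stay
on one side), and leave-one-year-out (LOO), where an entire year is predicted
from the others. Under LOO the year main effect and the year-by-line
interaction are not estimable for the held-out year and are removed from
every model; the network likewise drops its year tower.

## Genotype quality control and the relationship matrix

Markers are filtered in a fixed order: heterozygote fraction above 10%
removes the marker; surviving heterozygous calls are recoded to the majority
homozygote (ties go to `AA`); missingness above 20% and minor allele
frequency below 0.05 remove the marker; residual missing cells take the
column mean. MAF is computed on the 0/1 codes after the heterozygote recode
and before imputation, treating the rarer code as minor. A marker with all
calls missing has heterozygote fraction defined as zero and is removed by
the missingness rule, so no rule ever divides by zero.

With 0/1 (single-copy presence/absence) coding, the relationship matrix is
the centered cross-product `G = M M' / Σ p_k (1 − p_k)`, `M = X − 1 p'` —
the single-copy analogue of the classical allele-count formula. Columns with
`p_k` exactly 0 or 1 carry no information and are excluded from numerator
and denominator alike.

The deep learning model consumes the genomic information through
`Z_L L'` where `G = L' L` is the Cholesky factorization with `L` upper
triangular (so each record's genomic input row reconstructs `G` by inner
products). `G` from a finite marker panel is frequently singular;
`cholesky_factor()` escalates a diagonal jitter through
`1e-8 × 10^m, m = 0..6` until factorization succeeds and reports the jitter
used. The factor residual `‖L'L − (G + jitter·I)‖∞` stays below 1e-8 by
construction and is asserted in the tests.

## The GBLUP reaction-norm model

Each record is modeled as a general mean, a fixed year effect, a random line
effect `g ~ N(0, σ_g² G)`, a random year-by-line effect with covariance
`σ_Yg² (I ⊗ G)`, fixed NDVI coefficients with flat priors, and Gaussian
residuals. Variance priors are scaled inverse-chi-square in the convention
of Bayesian ridge software: degrees of freedom `df0 = 5` and scale chosen so
the prior mode matches an `R2 = 0.5` split of the sample variance of the
response, divided equally among the random terms present; the residual gets
the `1 − R2` share. Both are user-configurable.

Implementation choices:

* **Eigenbasis sampling.** `G = Γ Λ Γ'` once per fit; line effects are
  sampled as `a = Γ' g` with independent prior variances `σ_g² λ_j`, which
  makes the full conditional a single Cholesky solve per iteration, and the
  year-by-line term reuses the same basis independently within each year.
  Components with `λ_j` below `1e-8 × λ_max` are dropped. Predictions for
  lines without records fall out automatically: their rows of `Γ` map the
  posterior mean `a` back to the line scale, which is exactly how
  information borrows through `G`.
* **Fixed effects** are updated jointly from their Gaussian full conditional
  with a ridge of 1e-8 for rank safety (e.g. a one-hot year design plus an
  intercept).
* **Chain defaults** are 12,000 iterations, 2,000 burn-in, thinning 5 — all
  configurable; the tests and the acceptance script use shorter, documented
  chains (1,500–2,500 iterations) that we verified give the same posterior
  means on those problem sizes. Identical seeds give identical chains.
* **Heritability** is reported as
  `h² = σ_g² · mean(diag G) / (σ_g² · mean(diag G) + σ²)`, so it refers to
  the average line.

Two facts about this estimator are worth knowing, both established with an
independent MCMC implementation (JAGS) of the same model and priors, which
matches the package's sampler to three decimals. First, with a single record
per line and a near-identity `G`, `σ_g²` and `σ²` are only weakly identified
and the posterior of their ratio largely reflects the prior — replication
(lines repeated across years) is what identifies the split. The simulation
tests therefore use the generator's default two-year design. Second, even
with 300 lines replicated over two years, a trait that is pure noise gets a
posterior-mean heritability around 0.15, not 0: the df0 = 5 prior keeps the
variance away from zero at this sample size. The test suite asserts the
verified value (well below the prior's 0.5 center), not an idealized zero.

## The multimodal residual network

One tower per modality. Tower widths follow `N_l = max(1, floor(N1/2^(l−1)))`
for `l = 1..nHL` (the floor at 1 guards the halving sequence from reaching
zero). Consecutive hidden layers pair into residual blocks:

    dense(L2) → batch-norm → relu → dense(L2) → batch-norm
      → add skip (bias-free linear projection when widths differ) → relu → dropout

An odd trailing layer is a plain dense → batch-norm → relu → dropout. The
towers' final representations are concatenated into one linear output neuron
whose weights carry L2. Where the block wiring was open we followed the
standard residual-MLP reading: two dense layers per block, projection skips
across width changes, batch normalization applied after each dense layer and
before the activation, with the skip added after the second batch-norm and
before the final relu.

Training minimizes mean squared error plus the L2 penalties with Adam
(β₁ = 0.9, β₂ = 0.999), minibatches of 32, at most 128 epochs, a 10%
validation split taken from the final rows (used only as the tuning
objective), and a learning rate `lr · exp(−wd · t)` at epoch `t` (0-based).
Early stopping monitors the *training* loss with patience `Pat`: training
stops once the epoch loss has failed to improve for `Pat` consecutive epochs
(a patience of 0 stops at the first non-improvement). Dropout and L2 are
shared across all hidden layers; the output layer carries L2 only. Batch
normalization uses ε = 1e-3 and running-statistic momentum 0.9; a trailing
minibatch of size one is folded into the previous batch because batch
statistics need at least two rows. Inference runs with dropout off and batch
norm on its running statistics, so predictions are deterministic; training is
bit-reproducible given the seed (initialization, shuffling and dropout all
derive from it).

The engine is written in base R (forward, backprop, Adam). Backpropagation
is verified against finite differences to ~1e-8 in the tests, and the
parameter count of a built model is checked against a closed-form recount
over random configurations. Models are trained on the standardized response
(training statistics) inside the evaluation harness, with predictions mapped
back to the trait scale.

## Hyperparameter tuning

`bayesian_optimize()` minimizes a scalar objective (for networks: the
validation MSE of one training run; no inner CV) over a box domain covering
per-tower layer counts (1–4 for the year tower, 1–6 for genomic and NDVI),
first-layer widths (up to 16 / 1024 / 64 — zero lower bounds are exclusive,
so the minimum width after rounding is 1), L2 in (1e-8, 1e-2), dropout in
(1e-4, 0.5), log learning-rate decay in (ln 4e-5, ln 4e-1), patience up to
64, and log learning rate in (ln 1e-5, ln 1e-2). The surrogate is a
zero-mean Gaussian process on inputs scaled to the unit cube with a single
length-scale Matérn-5/2 kernel; length-scale and nugget maximize the
marginal likelihood. Acquisition is expected improvement, maximized over a
random candidate pool (500 uniform draws plus 50 local perturbations of the
incumbent); the initial design is a 10-point Latin hypercube. Integer
dimensions are rounded at evaluation time. A non-finite objective is
recorded with a large penalty so optimization continues. The reference
budget is 150 guided iterations; the command-line front end caps it at 20 by
default for desk-scale runs.

## Baselines

**Gradient boosting.** Squared-error stochastic gradient boosting with
depth-1 trees: the initial constant is the response mean; each iteration
draws a 50% subsample without replacement, fits the best stump to the
residuals, and adds it with shrinkage 0.001, for 5,000 iterations by default
with a minimum terminal-node size of 10. Under squared loss the per-leaf
means solve the line-search step exactly, so leaf constants absorb the step
size. The split criterion is squared-error reduction with candidate
thresholds at midpoints of consecutive distinct values; ties keep the lowest
feature index, then the lowest threshold; iterations with no admissible
split contribute nothing (constant features therefore leave the prediction
at the initial mean). The split search is compiled (C++), as is usual for
boosting implementations; it is tested against an exhaustive R search.

**Support vector regression.** Linear ε-insensitive SVR (ε = 0.1, cost
C = 1, tolerance 0.01) solved in the dual by sequential minimal optimization
with maximal-violating-pair selection and a second-order choice of the
partner variable, the intercept recovered from the box-interior gradient
bounds. The coefficient vector — not the intercept — is regularized. The
solver is compared in the tests against an independent SVM implementation
and against an interior-point solve of the same dual quadratic program. The
evaluation harness standardizes features and response before solving
(matching the reference implementation's default) and back-transforms.

## Metrics and the experiment grid

NRMSEP is RMSE divided by the mean of the observed test values: on a trait
with mean ≈ 600 and accuracy ≈ 0.7 this lands near 0.09, which is the
magnitude this diagnostic is expected to take; normalizing by the standard
deviation instead would pin it near `sqrt(1 − r²)` ≈ 0.7 and lose the
trait-scale reading. A zero observed mean is an error, as is a zero-variance
correlation (reported as a failure, never coerced to 0). Fold aggregates are
the mean and the sample (n−1) standard deviation across folds; LOO metrics
are computed on the single held-out set. Five-fold partitions shuffle lines
under the supplied seed and are identical across models, so model
comparisons are paired.

## The synthetic generator

`simulate_genotypes()` draws per-marker allele frequencies uniformly from
[0.05, 0.5] and samples binary genotypes independently per line;
heterozygous and missing calls can be injected at configurable rates to
exercise QC. `simulate_trial()` draws line genetic values with covariance
`σ_g² G` through the Cholesky factor, year (or year-environment) effects and
year-by-line effects at configured variance shares, and Gaussian residuals
scaled so `var(g)/(var(g)+var(e))` hits the target heritability. NDVI
timepoints are `0.6 + 0.08 (ρ g_std + sqrt(1−ρ²) z)` plus a small
year-by-timepoint offset, giving a within-year correlation ρ (default 0.5)
with the genetic value — so date-aligned and period-averaged covariate modes
differ meaningfully. Defaults mirror the motivating panel: 350 lines, two
cycles, trait scale like grain yield in g/m² (mean 600, phenotypic CV
≈ 0.12, year share 0.2, interaction share 0.1); the marker count defaults to
2,000, which is enough for a stable GRM at this panel size while keeping
simulation fast.

What the generator does **not** emulate: linkage disequilibrium (markers are
independent), spatial field-trial error and its design adjustment (the
package consumes already-adjusted phenotypes), selection structure or
pedigree relatedness beyond what random genotypes induce, and NDVI dynamics
richer than a shared genetic component with independent noise. Passing tests
therefore demonstrate that the estimators recover the structure they assume,
not that they rank identically on real trials.

## Problem sizes used by the tests and the acceptance script

Unit tests run on panels of 6–40 lines; the simulation-recovery tests use
300–500 lines; the acceptance script simulates the full 350-line two-year
panel with 2,000 markers, evaluates all four models under five-fold CV and
leave-one-year-out with documented short chains (1,500 iterations) and a
small untuned network (towers 8/64/8, 60 epochs), and recovers heritability
with a 2,500-iteration chain. These budgets were chosen so a complete run
takes a few minutes on one CPU; all chain lengths and epoch caps are
arguments, and the full-scale defaults (12,000 iterations; 128 epochs; 150
tuning iterations) remain available.

## Known limitations

* Pure R network training is practical for the tabular widths used here
  (inputs of a few hundred columns); image-sized inputs would need a
  compiled backend.
* The GBLUP sampler assumes a dense, time-invariant `G`; pedigree matrices
  and multi-trait models are out of scope.
* Variance-component ratios from small, unreplicated designs largely reflect
  the prior (see above); interpret heritability from such designs with care.
* The SVR solver is exact but dense (`O(n²)` kernel storage): fine for
  trial-sized data, not for tens of thousands of records.
* VCF/PLINK ingestion, LD pruning and population-structure correction are
  deliberately not provided; inputs are plain CSV/TSV matrices and tables.
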