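# mmgp — multimodal genomic prediction for plant breeding trials

`mmgp` is an R toolkit for genomic prediction in multi-year, multi-environment
wheat trials that links genome-wide markers with aerial canopy phenotypes
(NDVI). It is aimed at quantitative geneticists and breeders who want to
compare a conventional Bayesian GBLUP reaction-norm model against machine
learning alternatives — in particular a multimodal residual neural network
that keeps each input type (year, genomic, NDVI) in its own sub-network —
under the cross-validation schemes breeding programs actually care about:
predicting unobserved lines (five-fold CV by line) and predicting a whole
unobserved year or environment (leave-one-out).

## The models

**GBLUP reaction-norm model.** Each record of line *j* in year *i* is

    y_ij = mu + year_i + g_j + (year x g)_ij
           + sum_l beta_vg,l x_vg,jl + sum_l beta_gf,l x_gf,jl + e_ij

with `g ~ N(0, sigma_g^2 G)`, `(year x g) ~ N(0, sigma_Yg^2 (I ⊗ G))` and
`e ~ N(0, sigma^2 I)`. `G` is the VanRaden genomic relationship matrix built
from 0/1 marker codes, `G = M M' / Σ p_k (1 - p_k)` with `M` the centered
marker matrix. The NDVI covariates enter either date-aligned (4 vegetative +
2 grain-filling columns) or period-averaged (1 + 1). The model is fitted by
Gibbs sampling with flat priors on fixed effects and scaled-inverse-chi-square
priors (df 5, scale from an R² = 0.5 variance split) on the variances;
`fit_gblup()` works in the eigenbasis of `G` so line and interaction updates
are fast and lines without records are predicted through the relationship
matrix.

**Multimodal residual network.** One multilayer-perceptron tower per input
modality; hidden widths halve layer by layer (`N_l = floor(N1 / 2^(l-1))`),
consecutive layers form residual blocks (dense + batch-norm + relu →
dense + batch-norm, skip connection, relu, dropout), and the towers'
final representations are concatenated into a single linear output neuron
with L2 regularization. Training uses Adam, minibatches of 32, at most 128
epochs, a 10% validation split, an exponentially decaying learning rate
`lr · exp(-wd · t)` and early stopping on the training loss. The whole engine
(forward pass, backpropagation, batch-norm, dropout, Adam) is implemented in
base R and is bit-reproducible given a seed. `bayesian_optimize()` tunes the
hyperparameters (layer counts, widths, L2, dropout, log learning rate, decay,
patience) with a Matérn-5/2 Gaussian-process surrogate and expected
improvement over the documented search domain.

**Baselines.** `fit_gbm()` is from-scratch stochastic gradient boosting
(depth-1 trees, 5000 iterations, shrinkage 0.001, minimum node size 10,
bag fraction 0.5; split search in C++), and `fit_svr_linear()` solves linear
epsilon-insensitive support vector regression (eps 0.1, cost 1, tolerance
0.01) by SMO on the dual.

**Metrics.** `nrmsep()` is RMSE divided by the mean of the observed test
values; `pearson_cor()` is the Pearson correlation between observed and
predicted values. `run_experiment()` drives the model × predictor-set ×
fold grid and returns a long-format results table.

## Worked example

```r
library(mmgp)

# simulate a two-year wheat panel: 120 lines, 800 SNPs, h2 = 0.5
cfg  <- sim_config(J = 120, p = 800, h2 = 0.5, seed = 42)
geno <- simulate_genotypes(cfg)
trial <- simulate_trial(cfg, geno$coded)

# marker QC and the genomic relationship matrix
coded    <- apply_qc(geno$calls)
features <- cholesky_factor(vanraden_grm(coded))
print(coded)
#> coded_genotypes: 120 lines x 791 markers (removed: het 0, miss 0, maf 9; imputed 0 cells)

# five-fold cross-validation by line: GBLUP vs the multimodal network
spec <- predictor_spec(ndvi = c("vg", "gf"), ndvi_mode = "average")
plan <- kfold_by_line(trial$records$line, k = 5, seed = 42)
res <- run_experiment(
  trial$records, features, trial$ndvi,
  models = c("gblup", "mmdl"), specs = list(year_G_ndvi = spec), plan = plan,
  model_args = list(
    gblup = list(chain = gblup_chain(1500, 500, 2, seed = 42)),
    mmdl  = list(config = mmdl_config(lr = 0.003, max_epochs = 60, seed = 42))))
print(summarize_eval(res), digits = 3)
#>   model        spec ndvi_mode metric   mean      sd
#> 1 gblup year_G_ndvi   average    cor 0.6051 0.03130
#> 3 gblup year_G_ndvi   average nrmsep 0.0906 0.00482
#> 2  mmdl year_G_ndvi   average    cor 0.2441 0.15995
#> 4  mmdl year_G_ndvi   average nrmsep 0.1139 0.00795

# heritability from the reaction-norm fit on the full trial
blocks <- assemble_predictors(trial$records,
                              predictor_spec(include_year_by_G = TRUE), features)
fit <- fit_gblup(blocks, features, chain = gblup_chain(2500, 500, 2, seed = 42))
cat(sprintf("posterior-mean heritability: %.3f (simulated truth: 0.5)\n", fit$h2_hat))
#> posterior-mean heritability: 0.515 (simulated truth: 0.5)
```

The per-fold correlations (`cor`, higher is better) and normalized errors
(`nrmsep`, lower is better) read as: GBLUP predicts unobserved lines of this
small simulated panel with correlation ≈ 0.61 and an error of ≈ 9% of the
trait mean, while the (untuned, small) network reaches ≈ 0.24 — at this
panel size the linear mixed model has the advantage, consistent with what
larger benchmarks in this field typically find under CV by line. The
posterior-mean heritability recovers the simulated 0.5.

A command-line front end over the same functions is installed with the
package (`inst/cli/mmgp`): `simulate`, `qc`, `grm`, `fit`, `tune` and
`evaluate` subcommands, each writing a run manifest with input digests and
seeds.

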