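test_that("an intercept-only model recovers the sample mean", {
  set.seed(10)
  records <- trial_table(paste0("L", 1:50), "y1", rnorm(50, 7, 2))
  feats <- cholesky_factor(diag(50))
  feats$line_ids <- paste0("L", 1:50)
  blocks <- assemble_predictors(
    records, predictor_spec(include_year = FALSE, include_G = FALSE), feats)
  fit <- fit_gblup(blocks, feats, chain = gblup_chain(3000, 500, 2, seed = 1))
  mcse <- 2 * sd(records$value) / sqrt(50)
  expect_lt(abs(fit$beta_hat[["(Intercept)"]] - mean(records$value)), 2 * mcse)
})

test_that("identical seeds give identical chains", {
  sim <- tiny_sim(J = 15, p = 80, seed = 11)
  blocks <- assemble_predictors(sim$records, predictor_spec(), sim$features)
  f1 <- fit_gblup(blocks, sim$features, chain = gblup_chain(400, 100, 2, seed = 9))
  f2 <- fit_gblup(blocks, sim$features, chain = gblup_chain(400, 100, 2, seed = 9))
  expect_identical(f1$var_samples, f2$var_samples)
  expect_identical(f1$g_hat, f2$g_hat)
})

test_that("with fixed variances the posterior mean solves the mixed-model equations", {
  sim <- tiny_sim(J = 20, p = 100, seed = 12, years = "y1",
                  var_year = 0, var_gxe = 0, h2 = 0.6)
  spec <- predictor_spec(include_year = FALSE)
  blocks <- assemble_predictors(sim$records, spec, sim$features)
  s2 <- 900; s2g <- 1800
  fit <- fit_gblup(blocks, sim$features,
                   chain = gblup_chain(40000, 4000, 2, seed = 2),
                   fix_var = list(sigma2 = s2, sigma2_g = s2g))

  # direct generalized-least-squares / MME oracle in the same eigenbasis
  eg <- eigen(sim$features$G, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-8
  Q <- eg$vectors[blocks$line_index, keep, drop = FALSE]
  W <- matrix(1, nrow(Q), 1)
  C <- rbind(cbind(crossprod(W) / s2, crossprod(W, Q) / s2),
             cbind(crossprod(Q, W) / s2,
                   crossprod(Q) / s2 + diag(1 / (s2g * eg$values[keep]))))
  rhs <- rbind(crossprod(W, blocks$y) / s2, crossprod(Q, blocks$y) / s2)
  sol <- solve(C, rhs)
  fitted_mme <- as.vector(W %*% sol[1, ] + Q %*% sol[-1, ])
  fitted_gibbs <- predict_gblup(fit, blocks)
  expect_lt(max(abs(fitted_gibbs - fitted_mme)) / sd(fitted_mme), 1e-2)
})

test_that("training-set predictions are shrunken relative to the data", {
  sim <- tiny_sim(J = 30, p = 150, seed = 13)
  blocks <- assemble_predictors(
    sim$records, predictor_spec(include_year_by_G = TRUE), sim$features)
  fit <- fit_gblup(blocks, sim$features, chain = gblup_chain(1200, 400, 2, seed = 3))
  pred <- predict_gblup(fit, blocks)
  expect_true(all(is.finite(pred)))
  expect_lte(var(pred), var(blocks$y))
})

test_that("LOO predictions ignore year terms and respect design symmetry", {
  sim <- tiny_sim(J = 12, p = 80, seed = 14)
  # duplicate line: L002 genotype copied into L001
  X <- sim$geno$coded$X
  X[1, ] <- X[2, ]
  feats <- cholesky_factor(vanraden_grm(make_coded(X, sim$geno$coded$line_ids)))
  spec <- loo_adjust_spec(predictor_spec(include_year_by_G = TRUE))
  expect_false(spec$include_year)
  train <- which(sim$records$year == "2015-2016")
  blocks <- assemble_predictors(sim$records, spec, feats, train_idx = train)
  fit <- fit_gblup(subset_blocks(blocks, train), feats,
                   chain = gblup_chain(800, 300, 2, seed = 4))
  expect_false(any(grepl("2016", names(fit$beta_hat))))
  test_blocks <- subset_blocks(blocks, setdiff(seq_len(nrow(sim$records)), train))
  pred <- predict_gblup(fit, test_blocks)
  # identical lines -> identical genomic predictions in the held-out year
  expect_equal(pred[test_blocks$line_index == 1], pred[test_blocks$line_index == 2])
})

test_that("higher heritability gives better genetic-value recovery", {
  cors <- sapply(c(0.2, 0.8), function(h2) {
    cfg <- sim_config(J = 120, p = 400, years = "y1", var_year = 0,
                      var_gxe = 0, h2 = h2, seed = 21)
    geno <- simulate_genotypes(cfg)
    sim <- simulate_trial(cfg, geno$coded)
    blocks <- assemble_predictors(sim$records,
                                  predictor_spec(include_year = FALSE),
                                  sim$features)
    tr <- 1:90
    fit <- fit_gblup(subset_blocks(blocks, tr), sim$features,
                     chain = gblup_chain(1200, 400, 2, seed = 5))
    te <- 91:120
    cor(predict_gblup(fit, subset_blocks(blocks, te)), sim$truth$g[te])
  })
  expect_gt(cors[2], cors[1])
})

test_that("non-finite responses are rejected", {
  sim <- tiny_sim(J = 8, p = 40, seed = 15)
  blocks <- assemble_predictors(sim$records, predictor_spec(), sim$features)
  blocks$y[3] <- Inf
  expect_error(fit_gblup(blocks, sim$features), "non-finite response")
})
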