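test_that("NRMSEP matches hand arithmetic and is scale invariant", {
  expect_equal(nrmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmsep(c(2, 4), c(3, 3)), 1 / 3)
  obs <- c(2, 4, 9); pred <- c(3, 3, 7)
  expect_equal(nrmsep(5 * obs, 5 * pred), nrmsep(obs, pred))
  expect_error(nrmsep(c(-1, 1), c(0, 0)), "zero")
})

test_that("the correlation metric matches hand values and flags degeneracy", {
  expect_equal(pearson_cor(1:4, 1:4), 1)
  expect_equal(pearson_cor(1:4, -(1:4)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("five-fold partitions balance lines and keep line records together", {
  plan <- kfold_by_line(rep(paste0("L", 1:10), each = 2), k = 5, seed = 1)
  sizes <- lengths(plan$fold_lines)
  expect_equal(sort(sizes), rep(2L, 5))
  expect_setequal(unlist(plan$folds), 1:20)

  plan7 <- kfold_by_line(paste0("L", 1:7), k = 5, seed = 2)
  expect_equal(sort(lengths(plan7$fold_lines)), c(1L, 1L, 1L, 2L, 2L))

  # a line with records in 2 years lands in exactly one fold
  ids <- c("a", "b", "c", "d", "e", "a")
  plan2 <- kfold_by_line(ids, k = 5, seed = 3)
  fold_of_a <- which(sapply(plan2$folds, function(f) 1 %in% f))
  expect_true(6 %in% plan2$folds[[fold_of_a]])

  expect_identical(kfold_by_line(ids, 5, seed = 3)$folds, plan2$folds)
  expect_error(kfold_by_line(c("a", "b"), k = 5), "exceeds")
})

test_that("leave-one-out splits are complementary and label-driven", {
  sim <- tiny_sim(J = 6, p = 40, seed = 20)
  plan <- loo_split(sim$records, "2016-2017", "year")
  test <- plan$folds[[1]]
  expect_true(all(sim$records$year[test] == "2016-2017"))
  train <- setdiff(seq_len(nrow(sim$records)), test)
  expect_length(intersect(train, test), 0)
  expect_setequal(c(train, test), seq_len(nrow(sim$records)))
  swap <- loo_split(sim$records, "2015-2016", "year")
  expect_setequal(swap$folds[[1]], train)
  expect_error(loo_split(sim$records, "2099", "year"), "unknown label")
})

test_that("environment labels drive DS2-style splits", {
  sim <- tiny_sim(J = 6, p = 40, seed = 21, years = "y1",
                  environments = c("irrigated", "drought"))
  plan <- loo_split(sim$records, "drought", "environment")
  expect_true(all(sim$records$environment[plan$folds[[1]]] == "drought"))
})

test_that("an oracle model scores perfectly and the grid has full cardinality", {
  sim <- tiny_sim(J = 15, p = 60, seed = 22)
  oracle <- list(
    fit = function(blocks, features, train_idx, args) blocks,
    predict = function(fit, blocks, test_idx) blocks$y[test_idx])
  plan <- kfold_by_line(sim$records$line, k = 5, seed = 4)
  specs <- list(a = predictor_spec(),
                b = predictor_spec(ndvi = "gf", ndvi_mode = "average"))
  res <- run_experiment(sim$records, sim$features, sim$ndvi,
                        models = list(oracle = oracle), specs = specs,
                        plan = plan)
  expect_equal(nrow(res), 2 * 5 * 2)  # specs x folds x metrics
  expect_true(all(res$value[res$metric == "nrmsep"] == 0))
  expect_true(all(abs(res$value[res$metric == "cor"] - 1) < 1e-12))
})

test_that("a constant-mean model flags undefined correlation and NRMSEP checks out", {
  records <- trial_table(paste0("L", 1:6), "y1", c(10, 12, 8, 14, 9, 13))
  feats <- cholesky_factor(diag(6))
  feats$line_ids <- paste0("L", 1:6)
  const_model <- list(
    fit = function(blocks, features, train_idx, args) mean(blocks$y[train_idx]),
    predict = function(fit, blocks, test_idx) rep(fit, length(test_idx)))
  plan <- structure(list(scheme = "fivefold", unit = "line",
                         folds = list(4:6), seed = NULL), class = "split_plan")
  res <- run_experiment(records, feats, NULL, models = list(cm = const_model),
                        specs = list(g = predictor_spec(include_year = FALSE)),
                        plan = plan)
  expect_true(is.na(res$value[res$metric == "cor"]))
  f_hat <- mean(c(10, 12, 8))
  expect_equal(res$value[res$metric == "nrmsep"],
               sqrt(mean((c(14, 9, 13) - f_hat)^2)) / mean(c(14, 9, 13)))
})

test_that("fold aggregation is recomputable from per-fold values", {
  sim <- tiny_sim(J = 15, p = 60, seed = 23)
  oracle <- list(
    fit = function(blocks, features, train_idx, args) blocks,
    predict = function(fit, blocks, test_idx)
      blocks$y[test_idx] + seq_along(test_idx) * 0.5)
  plan <- kfold_by_line(sim$records$line, k = 5, seed = 5)
  res <- run_experiment(sim$records, sim$features, NULL,
                        models = list(noisy = oracle),
                        specs = list(g = predictor_spec()), plan = plan)
  summ <- summarize_eval(res)
  v <- res$value[res$metric == "nrmsep"]
  expect_equal(summ$mean[summ$metric == "nrmsep"], mean(v))
  expect_equal(summ$sd[summ$metric == "nrmsep"], sd(v))
})

test_that("identical seeds give identical partitions across models", {
  lines <- rep(paste0("L", 1:20), times = 2)
  p1 <- kfold_by_line(lines, 5, seed = 99)
  p2 <- kfold_by_line(lines, 5, seed = 99)
  expect_identical(p1$folds, p2$folds)
})
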