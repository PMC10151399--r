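# gradient boosting ----------------------------------------------------------

# Exhaustive stump search over all (feature, midpoint) candidates, used as
# the oracle for the compiled split finder.
brute_stump <- function(X, r, idx, min_node) {
  best <- NULL
  best_gain <- -1  # admissible gains are sums-of-squares over counts, >= 0
  for (j in seq_len(ncol(X))) {
    xs <- X[idx, j]
    for (thr in (head(sort(unique(xs)), -1) + diff(sort(unique(xs))) / 2)) {
      left <- idx[xs <= thr]; right <- idx[xs > thr]
      if (length(left) < min_node || length(right) < min_node) next
      gain <- sum(r[left])^2 / length(left) + sum(r[right])^2 / length(right)
      if (gain > best_gain + 1e-12 * (1 + abs(best_gain))) {
        best_gain <- gain
        best <- list(feature = j, threshold = thr,
                     left = mean(r[left]), right = mean(r[right]))
      }
    }
  }
  best
}

test_that("zero iterations predict the training mean everywhere", {
  f <- fit_gbm(matrix(1:4), c(0, 0, 1, 1), gbm_spec(M = 0))
  expect_equal(predict_gbm(f, matrix(c(-5, 100), 2)), c(0.5, 0.5))
  expect_equal(nrow(f$trees), 0L)
})

test_that("one stump on the step data reproduces the hand split", {
  x <- matrix(c(1, 2, 3, 4))
  y <- c(0, 0, 1, 1)
  f1 <- fit_gbm(x, y, gbm_spec(M = 1, shrinkage = 1, min_node = 1,
                               bag_fraction = 1, seed = 1))
  expect_equal(f1$trees[1, "threshold"], 2.5, ignore_attr = TRUE)
  expect_equal(predict_gbm(f1, matrix(4)), 1.0)
  f2 <- fit_gbm(x, y, gbm_spec(M = 1, shrinkage = 0.001, min_node = 1,
                               bag_fraction = 1, seed = 1))
  expect_equal(predict_gbm(f2, matrix(4)), 0.5005)
})

test_that("the training loss is non-increasing without subsampling", {
  set.seed(2)
  X <- matrix(rnorm(120 * 4), 120)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(120, sd = 0.3)
  f <- fit_gbm(X, y, gbm_spec(M = 400, shrinkage = 0.001, bag_fraction = 1,
                              seed = 3))
  expect_true(all(diff(f$train_loss) <= 1e-12))
})

test_that("subsampled fits are seed-reproducible and rows are exchangeable", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60)
  X[2, ] <- X[1, ]
  y <- rowSums(X) + rnorm(60, sd = 0.2)
  f1 <- fit_gbm(X, y, gbm_spec(M = 50, seed = 7))
  f2 <- fit_gbm(X, y, gbm_spec(M = 50, seed = 7))
  expect_identical(f1$trees, f2$trees)
  p <- predict_gbm(f1, X)
  expect_equal(p[1], p[2])  # identical rows, identical predictions
})

test_that("the compiled split finder agrees with exhaustive search", {
  for (s in 1:8) {
    set.seed(300 + s)
    n <- sample(20:50, 1); p <- sample(2:10, 1)
    X <- matrix(sample(seq(-2, 2, by = 0.25), n * p, replace = TRUE), n, p)
    r <- rnorm(n)
    idx <- sort(sample(n, max(10, n - 5)))
    got <- mmgp:::.best_stump_cpp(X, r, as.integer(idx), 3L)
    want <- brute_stump(X, r, idx, 3L)
    expect_equal(got$feature, want$feature, info = paste("seed", s))
    expect_equal(got$threshold, want$threshold, info = paste("seed", s))
    expect_equal(got$left, want$left, info = paste("seed", s))
    expect_equal(got$right, want$right, info = paste("seed", s))
  }
})

test_that("constant features leave the prediction at the initial constant", {
  f <- fit_gbm(matrix(1, 30, 2), rnorm(30, 5), gbm_spec(M = 20, seed = 1))
  expect_equal(nrow(f$trees), 0L)
  expect_equal(unique(predict_gbm(f, matrix(1, 4, 2))), f$f0)
})

test_that("feature-count mismatches are rejected", {
  f <- fit_gbm(matrix(rnorm(40), 20), rnorm(20), gbm_spec(M = 2, seed = 1))
  expect_error(predict_gbm(f, matrix(0, 3, 5)), "mismatch")
})

# support vector regression ---------------------------------------------------

test_that("a constant response gives zero coefficients and in-tube predictions", {
  set.seed(4)
  X <- matrix(rnorm(120), 40)
  f <- fit_svr_linear(X, rep(5, 40))
  expect_equal(max(abs(f$beta)), 0)
  expect_lt(max(abs(predict_svr(f, X) - 5)), 0.1 + 1e-8)
})

test_that("a clean linear signal is recovered within the tube tolerance", {
  set.seed(5)
  x <- matrix(seq(-1, 1, length.out = 60))
  y <- 2 * x[, 1] + runif(60, -0.05, 0.05)
  f <- fit_svr_linear(x, y)
  expect_lt(abs(f$beta - 2), 0.1)
})

test_that("vanishing cost shrinks the coefficients to zero", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50)
  y <- X[, 1] + rnorm(50, sd = 0.1)
  f <- fit_svr_linear(X, y, svr_spec(C = 1e-8))
  expect_lt(max(abs(f$beta)), 1e-6)
})

test_that("the solution is locally optimal for the primal objective", {
  set.seed(7)
  X <- matrix(rnorm(40 * 5), 40)
  y <- X %*% c(1, -0.5, 0, 0.3, 0) + rnorm(40, sd = 0.2)
  f <- fit_svr_linear(X, y)
  base <- svr_objective(X, y, f$beta0, f$beta)
  for (k in 1:50) {
    pert <- svr_objective(X, y, f$beta0 + rnorm(1, sd = 0.02),
                          f$beta + rnorm(5, sd = 0.02))
    expect_gte(pert, base - 1e-6)
  }
})

test_that("the solver matches an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  X <- matrix(rnorm(50 * 4), 50)
  y <- as.numeric(X %*% c(0.8, -1, 0.2, 0) + rnorm(50, sd = 0.3))
  f <- fit_svr_linear(X, y)
  sv <- e1071::svm(X, y, kernel = "linear", scale = FALSE,
                   epsilon = 0.1, cost = 1, tolerance = 0.01)
  beta_sv <- as.vector(t(sv$coefs) %*% sv$SV)
  obj_mine <- svr_objective(X, y, f$beta0, f$beta)
  obj_sv <- svr_objective(X, y, -sv$rho, beta_sv)
  expect_lt(abs(obj_mine - obj_sv) / obj_sv, 1e-3)
  expect_equal(f$beta, beta_sv, tolerance = 0.02)
})
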