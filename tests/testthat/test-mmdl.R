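# helpers for poking weights ------------------------------------------------

zeroed_model <- function(model) {
  zero_rec <- function(x) if (is.list(x)) lapply(x, zero_rec) else x * 0
  model$params <- zero_rec(model$params)
  model
}

single_unit_model <- function() {
  cfg <- mmdl_config(towers = list(g = list(nHL = 1, N1 = 1)),
                     lambda = 0, dropout = 0, seed = 1)
  m <- build_mmdl(list(g = 1L), cfg)
  m$params$towers$g[[1]]$W <- matrix(2, 1, 1)
  m$params$towers$g[[1]]$b <- 0
  m$params$towers$g[[1]]$gm <- 1
  m$params$towers$g[[1]]$bt <- 0
  m$state$towers$g[[1]]$rm <- 0
  m$state$towers$g[[1]]$rv <- 1
  m$params$fusion$W <- matrix(1, 1, 1)
  m$params$fusion$b <- 0
  m
}

test_that("hidden-layer widths halve with a floor of one", {
  expect_equal(layer_widths(16, 4), c(16L, 8L, 4L, 2L))
  expect_equal(layer_widths(16, 1), 16L)
  expect_equal(layer_widths(5, 3), c(5L, 2L, 1L))
  expect_equal(layer_widths(1, 4), rep(1L, 4))
})

test_that("the frozen single-unit network reproduces the hand forward pass", {
  m <- single_unit_model()
  # relu(2 * 3) through inference-mode BN (mean 0, var 1), output weight 1
  expect_equal(predict_mmdl(m, list(g = matrix(3, 1, 1))), 6, tolerance = 1e-2)
  expect_equal(predict_mmdl(m, list(g = matrix(-1, 1, 1))), 0, tolerance = 1e-6)
})

test_that("a zero network returns the output bias for any input", {
  cfg <- mmdl_config(towers = list(a = list(nHL = 2, N1 = 4),
                                   b = list(nHL = 1, N1 = 3)),
                     lambda = 0, dropout = 0, seed = 2)
  m <- zeroed_model(build_mmdl(list(a = 3L, b = 2L), cfg))
  x <- list(a = matrix(rnorm(15), 5), b = matrix(rnorm(10), 5))
  expect_equal(predict_mmdl(m, x), rep(0, 5))
})

test_that("the fusion layer width is the sum of tower output widths", {
  cfg <- mmdl_config(towers = list(a = list(nHL = 1, N1 = 4),
                                   b = list(nHL = 1, N1 = 8),
                                   c = list(nHL = 1, N1 = 2)), seed = 3)
  m <- build_mmdl(list(a = 2L, b = 2L, c = 2L), cfg)
  expect_equal(m$arch$fused_dim, 14L)
  expect_equal(nrow(m$params$fusion$W), 14L)
})

test_that("the parameter count matches a closed-form recount on random configs", {
  count_formula <- function(input_dims, cfg) {
    total <- 0L
    final <- 0L
    for (q in names(input_dims)) {
      widths <- layer_widths(cfg$towers[[q]]$N1, cfg$towers[[q]]$nHL)
      cur <- input_dims[[q]]
      l <- 1L
      while (l <= length(widths)) {
        if (l + 1L <= length(widths)) {
          h1 <- widths[l]; h2 <- widths[l + 1L]
          total <- total + cur * h1 + h1 + 2 * h1 +  # dense1 + BN1
            h1 * h2 + h2 + 2 * h2                    # dense2 + BN2
          if (cur != h2) total <- total + cur * h2   # projection
          cur <- h2; l <- l + 2L
        } else {
          h <- widths[l]
          total <- total + cur * h + h + 2 * h
          cur <- h; l <- l + 1L
        }
      }
      final <- final + cur
    }
    total + final + 1L  # fusion weights + bias
  }
  set.seed(4)
  for (rep in 1:20) {
    dims <- list(a = sample(1:30, 1), b = sample(1:30, 1))
    cfg <- mmdl_config(towers = list(a = list(nHL = sample(1:4, 1),
                                              N1 = sample(1:32, 1)),
                                     b = list(nHL = sample(1:5, 1),
                                              N1 = sample(1:64, 1))),
                       seed = rep)
    m <- build_mmdl(dims, cfg)
    expect_equal(mmdl_count_params(m), count_formula(dims, cfg))
  }
})

test_that("training is bit-reproducible given a seed", {
  set.seed(5)
  X <- list(genomic = matrix(rnorm(60 * 8), 60))
  y <- rnorm(60)
  cfg <- mmdl_config(towers = list(genomic = list(nHL = 2, N1 = 8)),
                     lambda = 0, dropout = 0, wd = 0, lr = 0.01,
                     max_epochs = 10, seed = 42)
  m1 <- train_mmdl(build_mmdl(list(genomic = 8L), cfg), X, y)
  m2 <- train_mmdl(build_mmdl(list(genomic = 8L), cfg), X, y)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  p <- predict_mmdl(m1, X)
  expect_identical(p, predict_mmdl(m1, X))  # inference determinism
})

test_that("training respects the epoch cap and fits a constant response", {
  set.seed(6)
  X <- list(genomic = matrix(rnorm(96 * 5), 96))
  y <- rep(0.8, 96)
  cfg <- mmdl_config(towers = list(genomic = list(nHL = 1, N1 = 4)),
                     lambda = 0, dropout = 0, lr = 0.02, wd = 0,
                     patience = 24, max_epochs = 128, seed = 7)
  m <- train_mmdl(build_mmdl(list(genomic = 5L), cfg), X, y)
  expect_lte(m$stopped_epoch, 128L)
  pred <- predict_mmdl(m, X)
  expect_lt(max(abs(pred - 0.8)), 0.05 * 0.8 + 0.05)
})

test_that("analytic gradients match finite differences", {
  getp <- function(x, path) { for (k in path) x <- x[[k]]; x }
  setp <- function(x, path, val) {
    if (length(path) == 1) { x[[path[[1]]]] <- val; x }
    else { x[[path[[1]]]] <- setp(x[[path[[1]]]], path[-1], val); x }
  }
  set.seed(8)
  cfg <- mmdl_config(towers = list(a = list(nHL = 3, N1 = 6),
                                   b = list(nHL = 2, N1 = 4)),
                     lambda = 1e-3, dropout = 0, seed = 9)
  m <- build_mmdl(list(a = 5L, b = 3L), cfg)
  X <- list(a = matrix(rnorm(35), 7), b = matrix(rnorm(21), 7))
  y <- rnorm(7)
  fw <- mmgp:::mmdl_forward(m, X, training = TRUE)
  gr <- mmgp:::mmdl_backward(m, X, fw, y)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fw2 <- mmgp:::mmdl_forward(m2, X, training = TRUE)
    mean((fw2$yhat - y)^2) + mmgp:::mmdl_l2_penalty(m2)
  }
  paths <- list(list("towers", "a", 1, "W1"), list("towers", "a", 1, "P"),
                list("towers", "a", 2, "W"), list("towers", "a", 1, "gm1"),
                list("towers", "b", 1, "bt2"), list("fusion", "W"))
  for (path in paths) {
    leaf <- getp(m$params, path)
    for (k in sample(length(leaf), min(3, length(leaf)))) {
      eps <- 1e-5
      up <- leaf; up[k] <- up[k] + eps
      dn <- leaf; dn[k] <- dn[k] - eps
      num <- (loss_at(setp(m$params, path, up)) -
                loss_at(setp(m$params, path, dn))) / (2 * eps)
      expect_equal(getp(gr, path)[k], num, tolerance = 1e-5)
    }
  }
})

test_that("dropping the year tower only changes the fusion width", {
  cfg <- mmdl_config(seed = 10)
  full <- build_mmdl(list(year = 2L, genomic = 12L, ndvi = 6L), cfg)
  loo <- build_mmdl(list(genomic = 12L, ndvi = 6L), cfg)
  expect_identical(full$arch$towers$genomic, loo$arch$towers$genomic)
  expect_identical(full$arch$towers$ndvi, loo$arch$towers$ndvi)
  expect_equal(full$arch$fused_dim - loo$arch$fused_dim,
               full$arch$towers$year$d_out)
})

test_that("dimension mismatches and unknown modalities fail loudly", {
  cfg <- mmdl_config(towers = list(g = list(nHL = 1, N1 = 4)), seed = 11)
  m <- build_mmdl(list(g = 5L), cfg)
  expect_error(predict_mmdl(m, list(g = matrix(0, 2, 4))), "expected 5 columns")
  expect_error(predict_mmdl(m, list(h = matrix(0, 2, 5))), "missing input")
  expect_error(build_mmdl(list(), cfg), "empty modality set")
})
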