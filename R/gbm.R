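# Stochastic gradient boosting with depth-1 regression trees (stumps),
# Gaussian loss, shrinkage and bagged subsampling.
#
# f0 is the mean of y (the squared-loss-optimal constant).  Each iteration
# draws a subsample without replacement, fits a stump to the negative
# gradient (the residual under Gaussian loss) on that subsample, and updates
# f <- f + nu * h.  Under squared loss the per-leaf means solve the
# line-search step exactly, so leaf constants absorb the step size.

#' Settings for the gradient boosting machine
#'
#' Defaults are the reference settings: 5000 trees, stumps, shrinkage 0.001,
#' minimum terminal-node size 10, bag fraction 0.5.
#'
#' @param M number of boosting iterations.
#' @param shrinkage learning rate `nu` in `(0, 1]`.
#' @param min_node minimum observations in each terminal node.
#' @param bag_fraction fraction of training rows subsampled (without
#'   replacement) per iteration, in `(0, 1]`.
#' @param seed RNG seed for the subsampling.
#' @return list of class `gbm_spec`.
#' @export
gbm_spec <- function(M = 5000, shrinkage = 0.001, min_node = 10,
                     bag_fraction = 0.5, seed = NULL) {
  stopifnot(M >= 0, shrinkage > 0, shrinkage <= 1,
            min_node >= 1, bag_fraction > 0, bag_fraction <= 1)
  structure(list(M = as.integer(M), shrinkage = shrinkage,
                 min_node = as.integer(min_node),
                 bag_fraction = bag_fraction, seed = seed),
            class = "gbm_spec")
}

#' Fit a stochastic gradient boosting ensemble
#'
#' @param X numeric feature matrix.
#' @param y numeric response, row-aligned with `X`.
#' @param spec a [gbm_spec].
#' @return object of class `gbm_fit`: `f0`, a matrix of stumps (feature,
#'   threshold, left and right leaf values, already shrunken), and
#'   `train_loss` (training MSE after each iteration).  Iterations where no
#'   admissible split exists contribute nothing.
#' @export
fit_gbm <- function(X, y, spec = gbm_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  f0 <- mean(y)
  f <- rep(f0, n)
  trees <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("feature", "threshold", "left", "right")))
  loss <- numeric(spec$M)
  n_bag <- max(2L, as.integer(floor(spec$bag_fraction * n)))

  with_seed(spec$seed, {
    for (t in seq_len(spec$M)) {
      idx <- if (n_bag < n) sample.int(n, n_bag) else seq_len(n)
      r <- y - f
      st <- .best_stump_cpp(X, r, as.integer(idx), spec$min_node)
      if (isTRUE(st$found)) {
        lv <- spec$shrinkage * st$left
        rv <- spec$shrinkage * st$right
        trees <- rbind(trees, c(st$feature, st$threshold, lv, rv))
        f <- f + ifelse(X[, st$feature] <= st$threshold, lv, rv)
      }
      loss[t] <- mean((y - f)^2)
    }
  })

  structure(list(f0 = f0, trees = trees, train_loss = loss, p = ncol(X),
                 spec = spec), class = "gbm_fit")
}

#' Predict from a boosted ensemble
#'
#' @param fit a [fit_gbm] result.
#' @param X feature matrix with the same columns as in training.
#' @return numeric vector: `f0` plus the sum of shrunken stump outputs.
#' @export
predict_gbm <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != fit$p) {
    stop_mmgp("feature count mismatch: model has %d, input has %d",
              fit$p, ncol(X))
  }
  pred <- rep(fit$f0, nrow(X))
  if (nrow(fit$trees)) {
    for (t in seq_len(nrow(fit$trees))) {
      tr <- fit$trees[t, ]
      pred <- pred + ifelse(X[, tr[["feature"]]] <= tr[["threshold"]],
                            tr[["left"]], tr[["right"]])
    }
  }
  pred
}

#' Write a boosted ensemble to disk
#'
#' Ensemble as JSON, training-loss path as CSV.
#'
#' @param fit a `gbm_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gbm <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(f0 = fit$f0, trees = as.data.frame(fit$trees)),
                       file.path(dir, "ensemble.json"), digits = NA)
  utils::write.csv(data.frame(iteration = seq_along(fit$train_loss),
                              train_mse = fit$train_loss),
                   file.path(dir, "loss_path.csv"), row.names = FALSE)
  invisible(dir)
}
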