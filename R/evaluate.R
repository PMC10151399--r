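# Cross-validation protocols, accuracy metrics and the experiment grid over
# models x predictor sets x NDVI modes.

#' Five-fold partition of records by line
#'
#' Lines (not records) are partitioned into `k` balanced folds, so all
#' records of a line fall on the same side of every split.
#'
#' @param line_ids per-record line identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return object of class `split_plan` with `scheme = "fivefold"`, `folds`
#'   (list of disjoint record index sets) and `fold_lines`.
#' @export
kfold_by_line <- function(line_ids, k = 5, seed = NULL) {
  lines <- unique(as.character(line_ids))
  if (k > length(lines)) stop_mmgp("k = %d exceeds number of lines (%d)", k, length(lines))
  with_seed(seed, {
    shuffled <- sample(lines)
    assign <- rep(seq_len(k), length.out = length(shuffled))
    fold_lines <- split(shuffled, assign)
    folds <- lapply(fold_lines, function(ls) which(as.character(line_ids) %in% ls))
    structure(list(scheme = "fivefold", unit = "line", k = k,
                   folds = unname(folds), fold_lines = unname(fold_lines),
                   seed = seed), class = "split_plan")
  })
}

#' Leave-one-year (or environment) out split
#'
#' The test set is every record carrying `holdout_label`; the training set is
#' everything else.
#'
#' @param records a [trial_table].
#' @param holdout_label the year or environment label to hold out.
#' @param unit `"year"` or `"environment"`.
#' @return a `split_plan` with a single fold (the held-out records).
#' @export
loo_split <- function(records, holdout_label, unit = "year") {
  labels <- context_labels(records, unit)
  if (!holdout_label %in% labels) stop_mmgp("unknown label '%s'", holdout_label)
  if (length(unique(labels)) < 2L) stop_mmgp("need at least 2 %s labels", unit)
  structure(list(scheme = "loo", unit = unit, holdout = holdout_label,
                 folds = list(which(labels == holdout_label)), seed = NULL),
            class = "split_plan")
}

#' Normalized root mean squared error of prediction
#'
#' RMSE divided by the mean of the observed values, so the error reads as a
#' fraction of the trait's typical magnitude.
#'
#' @param obs,pred numeric vectors of equal length >= 2.
#' @return scalar NRMSEP.
#' @export
nrmsep <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  m <- mean(obs)
  if (abs(m) < 1e-12) {
    stop_mmgp("mean of observed values is zero; normalize by the SD instead")
  }
  sqrt(mean((obs - pred)^2)) / m
}

#' Pearson correlation between observed and predicted values
#'
#' @param obs,pred numeric vectors of equal length >= 3 with nonzero
#'   variance; zero variance is an error, not a zero.
#' @return scalar correlation.
#' @export
pearson_cor <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3)
  if (stats::sd(obs) < 1e-12 || stats::sd(pred) < 1e-12) {
    stop_mmgp("zero variance: correlation undefined")
  }
  stats::cor(obs, pred)
}

# ---- model registry -------------------------------------------------------

# A model entry is list(fit = function(blocks, features, train_idx, args),
# predict = function(fit, blocks, test_idx)).  Blocks are assembled once per
# fold with training-set NDVI statistics, then subset.

flatten_blocks <- function(blocks) {
  mats <- Filter(Negate(is.null),
                 list(blocks$X_year, blocks$Z, blocks$X_ndvi))
  if (!length(mats)) stop_mmgp("predictor spec selects no inputs")
  do.call(cbind, mats)
}

modality_inputs <- function(blocks) {
  inputs <- list()
  if (!is.null(blocks$X_year)) inputs$year <- blocks$X_year
  if (!is.null(blocks$Z)) inputs$genomic <- blocks$Z
  if (!is.null(blocks$X_ndvi)) inputs$ndvi <- blocks$X_ndvi
  inputs
}

model_registry <- function() {
  list(
    gblup = list(
      fit = function(blocks, features, train_idx, args) {
        chain <- args$chain %||% gblup_chain()
        fit_gblup(subset_blocks(blocks, train_idx), features, chain = chain)
      },
      predict = function(fit, blocks, test_idx) {
        predict_gblup(fit, subset_blocks(blocks, test_idx))
      }),
    mmdl = list(
      # the network trains on the standardized response (training statistics)
      # and predictions are mapped back to the trait scale
      fit = function(blocks, features, train_idx, args) {
        inputs <- modality_inputs(subset_blocks(blocks, train_idx))
        cfg <- args$config %||% mmdl_config()
        cfg$towers <- cfg$towers[names(cfg$towers) %in% names(inputs)]
        model <- build_mmdl(lapply(inputs, ncol), cfg)
        y <- blocks$y[train_idx]
        ctr <- mean(y); scl <- stats::sd(y)
        if (!is.finite(scl) || scl < 1e-12) scl <- 1
        model <- train_mmdl(model, inputs, (y - ctr) / scl)
        model$y_center <- ctr; model$y_scale <- scl
        model
      },
      predict = function(fit, blocks, test_idx) {
        p <- predict_mmdl(fit, modality_inputs(subset_blocks(blocks, test_idx)))
        fit$y_center + fit$y_scale * p
      }),
    gbm = list(
      fit = function(blocks, features, train_idx, args) {
        spec <- args$spec %||% gbm_spec()
        fit_gbm(flatten_blocks(subset_blocks(blocks, train_idx)),
                blocks$y[train_idx], spec)
      },
      predict = function(fit, blocks, test_idx) {
        predict_gbm(fit, flatten_blocks(subset_blocks(blocks, test_idx)))
      }),
    svr = list(
      # standardize features and response before solving (the reference
      # implementation's default behavior), back-transform predictions
      fit = function(blocks, features, train_idx, args) {
        spec <- args$spec %||% svr_spec()
        X <- flatten_blocks(subset_blocks(blocks, train_idx))
        y <- blocks$y[train_idx]
        xc <- colMeans(X); xs <- apply(X, 2L, stats::sd)
        xs[!is.finite(xs) | xs < 1e-12] <- 1
        ctr <- mean(y); scl <- stats::sd(y)
        if (!is.finite(scl) || scl < 1e-12) scl <- 1
        fit <- fit_svr_linear(sweep(sweep(X, 2L, xc, "-"), 2L, xs, "/"),
                              (y - ctr) / scl, spec)
        fit$x_center <- xc; fit$x_scale <- xs
        fit$y_center <- ctr; fit$y_scale <- scl
        fit
      },
      predict = function(fit, blocks, test_idx) {
        X <- flatten_blocks(subset_blocks(blocks, test_idx))
        X <- sweep(sweep(X, 2L, fit$x_center, "-"), 2L, fit$x_scale, "/")
        fit$y_center + fit$y_scale * predict_svr(fit, X)
      })
  )
}

#' Run a cross-validated experiment grid
#'
#' For each model and predictor spec, assembles predictor blocks per fold
#' (NDVI standardized with training statistics), fits on the training side,
#' predicts the test side and computes NRMSEP and Pearson correlation.
#'
#' @param records a [trial_table].
#' @param features a `genomic_features` object (Cholesky-completed).
#' @param ndvi an [ndvi_table] or NULL.
#' @param models character vector among `"gblup"`, `"mmdl"`, `"gbm"`,
#'   `"svr"`, or a named list of custom entries `list(fit=, predict=)`.
#' @param specs named list of [predictor_spec]s (names label the rows).
#' @param plan a [kfold_by_line] or [loo_split] plan.  Under a LOO plan the
#'   year/environment terms are dropped from every spec.
#' @param model_args named list (by model) of extra arguments, e.g.
#'   `list(gblup = list(chain = gblup_chain(2000, 500, seed = 1)))`.
#' @return data.frame of class `eval_result`, long format: model, spec,
#'   ndvi_mode, fold, metric, value; aggregate with [summarize_eval].
#' @export
run_experiment <- function(records, features, ndvi = NULL, models, specs,
                           plan, model_args = list()) {
  registry <- model_registry()
  if (is.character(models)) {
    unknown <- setdiff(models, names(registry))
    if (length(unknown)) stop_mmgp("unknown model(s): %s", paste(unknown, collapse = ", "))
    models <- stats::setNames(registry[models], models)
  }
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  n <- nrow(records)
  rows <- list()
  for (mname in names(models)) {
    for (sname in names(specs)) {
      spec <- specs[[sname]]
      if (plan$scheme == "loo") spec <- loo_adjust_spec(spec)
      for (f in seq_along(plan$folds)) {
        test_idx <- plan$folds[[f]]
        train_idx <- setdiff(seq_len(n), test_idx)
        blocks <- assemble_predictors(records, spec, features, ndvi = ndvi,
                                      train_idx = train_idx,
                                      unit = if (plan$scheme == "loo") plan$unit else "year")
        fit <- tryCatch(
          models[[mname]]$fit(blocks, features, train_idx,
                              model_args[[mname]] %||% list()),
          error = function(e) stop_mmgp("model '%s', fold %d: %s", mname, f,
                                        conditionMessage(e)))
        pred <- models[[mname]]$predict(fit, blocks, test_idx)
        obs <- records$value[test_idx]
        cor_val <- tryCatch(pearson_cor(obs, pred), error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mname, spec = sname, ndvi_mode = spec$ndvi_mode, fold = f,
          metric = c("nrmsep", "cor"),
          value = c(nrmsep(obs, pred), cor_val),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_result", "data.frame")
  out
}

#' Aggregate an experiment table across folds
#'
#' @param result an [run_experiment] table.
#' @return data.frame with the mean and sample standard deviation (n - 1)
#'   of each metric across folds.
#' @export
summarize_eval <- function(result) {
  agg <- stats::aggregate(value ~ model + spec + ndvi_mode + metric,
                          data = result,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- cbind(agg[, c("model", "spec", "ndvi_mode", "metric")],
               mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  out[order(out$model, out$spec, out$metric), ]
}
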