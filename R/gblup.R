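# Bayesian GBLUP reaction-norm model fitted by Gibbs sampling.
#
# y = W beta + Z g + u + e,   g ~ N(0, s2_g G),  u ~ N(0, s2_u (I_I x G)),
# e ~ N(0, s2 I), flat priors on the fixed effects (intercept, year, NDVI)
# and scaled-inverse-chi-square priors on the three variances.  G enters
# through its eigendecomposition G = Gamma Lambda Gamma', which orthogonalizes
# the line effects (a = Gamma' g) and lets the year-by-line interaction reuse
# the same basis independently within each year.

#' Chain settings for the Gibbs sampler
#'
#' @param n_iter total iterations (default 12000).
#' @param burn_in discarded warm-up iterations (default 2000).
#' @param thin keep every `thin`-th post-burn-in draw (default 5).
#' @param seed RNG seed; identical seeds give identical chains.
#' @return list of class `gblup_chain`.
#' @export
gblup_chain <- function(n_iter = 12000, burn_in = 2000, thin = 5, seed = NULL) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed), class = "gblup_chain")
}

#' Fit the Bayesian GBLUP reaction-norm model
#'
#' Variance priors follow the usual Bayesian ridge convention: degrees of
#' freedom `df0` and scale chosen so the prior mode matches the `R2`-partition
#' of the sample variance of the response, split equally among the random
#' terms present (the residual receives the `1 - R2` share).
#'
#' @param blocks predictor blocks from [assemble_predictors] (training rows).
#' @param features the `genomic_features` object used to build `blocks`.
#' @param chain a [gblup_chain].
#' @param df0 prior degrees of freedom (default 5).
#' @param R2 prior variance-partition fraction (default 0.5).
#' @param fix_var optional list `(sigma2, sigma2_g, sigma2_u)` holding the
#'   variances fixed instead of sampling them (used for validation against a
#'   direct generalized-least-squares solve).
#' @return Object of class `gblup_fit`: posterior means of fixed effects
#'   (`beta_hat`), line effects (`g_hat`), year-by-line effects (`u_hat`),
#'   variances (`var_hat`), heritability `h2_hat = s2_g / (s2_g + s2)`, and
#'   retained variance samples for diagnostics.
#' @export
fit_gblup <- function(blocks, features, chain = gblup_chain(),
                      df0 = 5, R2 = 0.5, fix_var = NULL) {
  stopifnot(df0 > 0, R2 > 0, R2 < 1)
  y <- blocks$y
  if (any(!is.finite(y))) stop_mmgp("non-finite response")
  n <- length(y)
  spec <- blocks$spec
  W <- gblup_design(blocks)
  p <- ncol(W)

  use_g <- isTRUE(spec$include_G)
  use_u <- isTRUE(spec$include_year_by_G)

  eg <- eigen(features$G, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-8
  Gamma <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  K <- length(lam)
  Q <- Gamma[blocks$line_index, , drop = FALSE]

  year_groups <- split(seq_len(n), blocks$year_index)
  I <- length(year_groups)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  n_rand <- sum(c(use_g, use_u))
  R2_term <- if (n_rand > 0) R2 / n_rand else R2
  mdG <- mean(diag(features$G))
  S_g <- vy * R2_term * (df0 + 2) / mdG
  S_u <- S_g
  S_e <- vy * (1 - R2) * (df0 + 2)

  s2 <- if (!is.null(fix_var)) fix_var$sigma2 else vy * (1 - R2)
  s2g <- if (!is.null(fix_var)) fix_var$sigma2_g %||% 0 else vy * R2_term / mdG
  s2u <- if (!is.null(fix_var)) fix_var$sigma2_u %||% 0 else vy * R2_term / mdG

  WtW <- crossprod(W)
  QtQ <- if (use_g) crossprod(Q) else NULL
  QtQ_year <- if (use_u) lapply(year_groups, function(r)
    crossprod(Q[r, , drop = FALSE])) else NULL

  beta <- c(mean(y), rep(0, p - 1L))
  a <- rep(0, K)
  b <- if (use_u) matrix(0, K, I) else NULL
  e <- y - as.vector(W %*% beta)

  keep_iters <- seq(chain$burn_in + chain$thin, chain$n_iter, by = chain$thin)
  n_keep <- length(keep_iters)
  sum_beta <- rep(0, p); sum_a <- rep(0, K)
  sum_b <- if (use_u) matrix(0, K, I) else NULL
  var_samples <- matrix(NA_real_, n_keep, 3,
                        dimnames = list(NULL, c("sigma2_g", "sigma2_u", "sigma2")))
  kept <- 0L
  ridge <- 1e-8

  draw_gauss <- function(C, rhs) {
    # sample from N(C^{-1} rhs, C^{-1})
    U <- chol(C)
    mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
    as.vector(mu + backsolve(U, stats::rnorm(length(rhs))))
  }

  with_seed(chain$seed, {
    for (it in seq_len(chain$n_iter)) {
      # fixed effects (flat prior, joint Gaussian full conditional)
      yres <- e + as.vector(W %*% beta)
      beta <- draw_gauss(WtW / s2 + diag(ridge, p), crossprod(W, yres) / s2)
      e <- yres - as.vector(W %*% beta)

      if (use_g) {
        yres <- e + as.vector(Q %*% a)
        a <- draw_gauss(QtQ / s2 + diag(1 / (s2g * lam), K),
                        crossprod(Q, yres) / s2)
        e <- yres - as.vector(Q %*% a)
      }
      if (use_u) {
        for (i in seq_len(I)) {
          r <- year_groups[[i]]
          Qi <- Q[r, , drop = FALSE]
          yres_i <- e[r] + as.vector(Qi %*% b[, i])
          b[, i] <- draw_gauss(QtQ_year[[i]] / s2 + diag(1 / (s2u * lam), K),
                               crossprod(Qi, yres_i) / s2)
          e[r] <- yres_i - as.vector(Qi %*% b[, i])
        }
      }
      if (is.null(fix_var)) {
        if (use_g) s2g <- (S_g + sum(a^2 / lam)) / stats::rchisq(1, df0 + K)
        if (use_u) s2u <- (S_u + sum(b^2 / lam)) / stats::rchisq(1, df0 + K * I)
        s2 <- (S_e + sum(e^2)) / stats::rchisq(1, df0 + n)
      }
      if (!all(is.finite(e)) || !is.finite(s2)) {
        stop_mmgp("chain divergence: non-finite draw at iteration %d", it)
      }
      if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
        kept <- kept + 1L
        sum_beta <- sum_beta + beta
        sum_a <- sum_a + a
        if (use_u) sum_b <- sum_b + b
        var_samples[kept, ] <- c(if (use_g) s2g else NA, if (use_u) s2u else NA, s2)
      }
    }
  })

  beta_hat <- sum_beta / kept
  names(beta_hat) <- colnames(W)
  a_hat <- sum_a / kept
  g_hat <- as.vector(Gamma %*% a_hat)
  names(g_hat) <- blocks$line_ids
  u_hat <- NULL
  if (use_u) {
    u_hat <- Gamma %*% (sum_b / kept)
    dimnames(u_hat) <- list(blocks$line_ids, names(year_groups))
    colnames(u_hat) <- blocks$year_levels[as.integer(names(year_groups))]
  }
  var_hat <- colMeans(var_samples[seq_len(kept), , drop = FALSE])
  h2_hat <- if (use_g) var_hat["sigma2_g"] * mdG /
    (var_hat["sigma2_g"] * mdG + var_hat["sigma2"]) else NA_real_

  structure(list(beta_hat = beta_hat, g_hat = g_hat, u_hat = u_hat,
                 var_hat = var_hat, h2_hat = unname(h2_hat),
                 var_samples = var_samples[seq_len(kept), , drop = FALSE],
                 spec = spec, year_levels = blocks$year_levels,
                 line_ids = blocks$line_ids, chain = chain),
            class = "gblup_fit")
}

# Fixed-effect design: intercept, year dummies with the first (alphabetical)
# level absorbed by the intercept, then the standardized NDVI columns.
gblup_design <- function(blocks) {
  n <- length(blocks$y)
  W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(blocks$X_year) && ncol(blocks$X_year) > 1L) {
    W <- cbind(W, blocks$X_year[, -1L, drop = FALSE])
  }
  if (!is.null(blocks$X_ndvi)) W <- cbind(W, blocks$X_ndvi)
  W
}

#' Predict phenotype records from a fitted GBLUP model
#'
#' Prediction is the fixed-effect part plus the posterior-mean line effect
#' (and year-by-line effect when the model contains it).  Lines unobserved in
#' training borrow information through the relationship matrix: their effects
#' come from the shared eigenbasis of `G`.  Records in years absent from
#' training receive no year or interaction contribution.
#'
#' @param fit a [fit_gblup] result.
#' @param blocks predictor blocks for the records to predict (built against
#'   the same `genomic_features`, e.g. via [subset_blocks]).
#' @return numeric vector of predictions.
#' @export
predict_gblup <- function(fit, blocks) {
  n <- length(blocks$y %||% blocks$line_index)
  beta <- fit$beta_hat
  pred <- rep(beta[["(Intercept)"]], n)
  if (fit$spec$include_year && !is.null(blocks$X_year)) {
    for (lv in colnames(blocks$X_year)) {
      if (lv %in% names(beta)) pred <- pred + blocks$X_year[, lv] * beta[[lv]]
    }
  }
  if (!is.null(blocks$X_ndvi)) {
    for (cn in colnames(blocks$X_ndvi)) {
      if (!cn %in% names(beta)) stop_mmgp("NDVI column '%s' unseen in training", cn)
      pred <- pred + blocks$X_ndvi[, cn] * beta[[cn]]
    }
  }
  if (fit$spec$include_G) {
    idx <- blocks$line_index
    if (any(idx < 1L | idx > length(fit$g_hat))) stop_mmgp("unknown line in prediction")
    pred <- pred + fit$g_hat[idx]
  }
  if (fit$spec$include_year_by_G && !is.null(fit$u_hat)) {
    yl <- blocks$year_levels[blocks$year_index]
    hit <- match(yl, colnames(fit$u_hat))
    ok <- !is.na(hit)
    if (any(ok)) {
      pred[ok] <- pred[ok] + fit$u_hat[cbind(blocks$line_index[ok], hit[ok])]
    }
  }
  unname(pred)
}

#' Subset assembled predictor blocks by record rows
#'
#' Keeps the global year levels and line ids so that train and test blocks
#' remain mutually consistent.
#'
#' @param blocks an [assemble_predictors] result.
#' @param idx record row indices to keep.
#' @return blocks restricted to `idx`.
#' @export
subset_blocks <- function(blocks, idx) {
  out <- blocks
  out$y <- blocks$y[idx]
  for (nm in c("X_year", "Z", "X_ndvi")) {
    if (!is.null(blocks[[nm]])) out[[nm]] <- blocks[[nm]][idx, , drop = FALSE]
  }
  out$line_index <- blocks$line_index[idx]
  out$year_index <- blocks$year_index[idx]
  out
}

#' Write a posterior summary to disk
#'
#' Effect tables as CSV, variances and chain settings as JSON.
#'
#' @param fit a `gblup_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gblup <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(effect = names(fit$beta_hat), estimate = fit$beta_hat),
                   file.path(dir, "fixed_effects.csv"), row.names = FALSE)
  utils::write.csv(data.frame(line = names(fit$g_hat), g_hat = fit$g_hat),
                   file.path(dir, "line_effects.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(var_hat = as.list(fit$var_hat), h2_hat = fit$h2_hat,
         chain = fit$chain[c("n_iter", "burn_in", "thin")]),
    file.path(dir, "posterior.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
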