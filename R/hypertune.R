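# Bayesian optimization of the network hyperparameters: Gaussian-process
# surrogate (Matern 5/2 kernel) with the expected-improvement acquisition,
# seeded by a Latin-hypercube initial design.

#' Hyperparameter search space
#'
#' Defaults reproduce the tuning domain of the multimodal model: per-tower
#' hidden-layer counts and first-layer widths, shared L2 coefficient, dropout
#' rate, log learning-decay (`lwd = ln(wd)`), early-stopping patience and log
#' learning rate (`llr = ln(lr)`).  Integer dimensions are rounded after the
#' continuous proposal; width lower bounds are exclusive at 0, so the
#' smallest width after rounding is 1.
#'
#' @param params named list; each element `list(lower, upper, integer)`.
#' @return list of class `hyper_space`.
#' @export
hyper_space <- function(params = NULL) {
  if (is.null(params)) {
    params <- list(
      nHL1 = list(lower = 1, upper = 4, integer = TRUE),
      nHL2 = list(lower = 1, upper = 6, integer = TRUE),
      nHL3 = list(lower = 1, upper = 6, integer = TRUE),
      N1_1 = list(lower = 1, upper = 16, integer = TRUE),
      N1_2 = list(lower = 1, upper = 1024, integer = TRUE),
      N1_3 = list(lower = 1, upper = 64, integer = TRUE),
      lambda = list(lower = 1e-8, upper = 1e-2, integer = FALSE),
      DO = list(lower = 1e-4, upper = 0.5, integer = FALSE),
      lwd = list(lower = log(4e-5), upper = log(4e-1), integer = FALSE),
      Pat = list(lower = 1, upper = 64, integer = TRUE),
      llr = list(lower = log(1e-5), upper = log(1e-2), integer = FALSE))
  }
  for (p in params) stopifnot(p$lower < p$upper)
  structure(params, class = "hyper_space")
}

space_decode <- function(space, u) {
  # u in [0,1]^d -> named config values, integers rounded
  out <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    val <- p$lower + u[i] * (p$upper - p$lower)
    if (isTRUE(p$integer)) val <- as.integer(round(val))
    out[[names(space)[i]]] <- val
  }
  out
}

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

gp_fit <- function(U, y) {
  # zero-mean GP on standardized y; single length-scale Matern 5/2 kernel;
  # length-scale and noise chosen by marginal likelihood
  mu <- mean(y); sg <- stats::sd(y)
  if (!is.finite(sg) || sg < 1e-12) sg <- 1
  ys <- (y - mu) / sg
  D <- as.matrix(stats::dist(U))
  nll <- function(theta) {
    ell <- exp(theta[1]); nug <- exp(theta[2])
    K <- matern52(D, ell) + diag(nug + 1e-8, nrow(U))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))))
  }
  opt <- stats::optim(c(log(0.3), log(1e-2)), nll, method = "L-BFGS-B",
                      lower = c(log(0.01), log(1e-6)),
                      upper = c(log(10), log(1)))
  ell <- exp(opt$par[1]); nug <- exp(opt$par[2])
  K <- matern52(D, ell) + diag(nug + 1e-8, nrow(U))
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
  list(U = U, ch = ch, alpha = alpha, ell = ell, nug = nug, mu = mu, sg = sg)
}

gp_predict <- function(gp, Unew) {
  Dx <- sqrt(outer(rowSums(Unew^2), rowSums(gp$U^2), "+") -
               2 * tcrossprod(Unew, gp$U))
  Dx[!is.finite(Dx) | Dx < 0] <- 0
  Ks <- matern52(Dx, gp$ell)
  mean_s <- as.vector(Ks %*% gp$alpha)
  V <- backsolve(gp$ch, t(Ks), transpose = TRUE)
  var_s <- pmax(1 + gp$nug - colSums(V^2), 1e-12)
  list(mean = gp$mu + gp$sg * mean_s, sd = gp$sg * sqrt(var_s))
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian optimization over a hyperparameter space
#'
#' Runs `n_init` Latin-hypercube evaluations followed by `n_iter` evaluations
#' guided by a Gaussian-process surrogate with the expected-improvement
#' acquisition (maximized over a random candidate pool each iteration).
#' A non-finite objective value is recorded with a large penalty and the
#' optimization continues.
#'
#' @param objective function taking a named config list (decoded, integers
#'   rounded) and returning a scalar to minimize, e.g. a validation MSE.
#' @param space a [hyper_space].
#' @param n_iter guided iterations (default 150, as in the tuning protocol;
#'   cap it for desk-scale runs).
#' @param n_init initial design size (default 10).
#' @param seed RNG seed; identical seeds give identical traces.
#' @param n_candidates EI candidate-pool size per iteration.
#' @return list of class `tune_result`: `best_config`, `best_objective`,
#'   `trace` (data.frame of all evaluations in order) and `seed`.
#' @export
bayesian_optimize <- function(objective, space = hyper_space(), n_iter = 150,
                              n_init = 10, seed = NULL, n_candidates = 500) {
  stopifnot(n_iter >= 1, n_init >= 1)
  d <- length(space)
  evals_u <- matrix(NA_real_, n_init + n_iter, d)
  evals_y <- numeric(n_init + n_iter)
  configs <- vector("list", n_init + n_iter)

  eval_point <- function(u, k) {
    cfg <- space_decode(space, u)
    val <- tryCatch(objective(cfg), error = function(e) NaN)
    if (!is.finite(val)) {
      done <- evals_y[seq_len(k - 1L)]
      done <- done[is.finite(done)]
      spread <- if (length(done) > 1L) stats::sd(done) else 1
      val <- if (length(done)) max(done) + 10 * max(spread, 1) else 1e6
      if (!is.finite(val)) val <- 1e6
    }
    list(cfg = cfg, val = val)
  }

  with_seed(seed, {
    U0 <- lhs::randomLHS(n_init, d)
    for (k in seq_len(n_init)) {
      r <- eval_point(U0[k, ], k)
      evals_u[k, ] <- U0[k, ]; evals_y[k] <- r$val; configs[[k]] <- r$cfg
    }
    for (it in seq_len(n_iter)) {
      k <- n_init + it
      done <- seq_len(k - 1L)
      gp <- tryCatch(gp_fit(evals_u[done, , drop = FALSE], evals_y[done]),
                     error = function(e) NULL)
      if (is.null(gp)) {
        u <- stats::runif(d)
      } else {
        cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
        # add local perturbations around the incumbent
        inc <- evals_u[done[which.min(evals_y[done])], ]
        loc <- matrix(rep(inc, each = 50), 50, d) +
          matrix(stats::rnorm(50 * d, sd = 0.05), 50, d)
        cand <- rbind(cand, pmin(pmax(loc, 0), 1))
        pr <- gp_predict(gp, cand)
        ei <- expected_improvement(pr$mean, pr$sd, min(evals_y[done]))
        u <- cand[which.max(ei), ]
      }
      r <- eval_point(u, k)
      evals_u[k, ] <- u; evals_y[k] <- r$val; configs[[k]] <- r$cfg
    }
  })

  trace <- cbind(as.data.frame(do.call(rbind, lapply(configs, function(cf)
    unlist(cf)))), objective = evals_y)
  trace$best_so_far <- cummin(evals_y)
  best_k <- which.min(evals_y)
  structure(list(best_config = configs[[best_k]],
                 best_objective = evals_y[best_k],
                 trace = trace, seed = seed),
            class = "tune_result")
}

#' Map a decoded hyperparameter configuration to an [mmdl_config]
#'
#' Tower 1 is the year modality, tower 2 genomic, tower 3 NDVI; towers absent
#' from `modalities` are skipped (e.g. no year tower under
#' leave-one-year-out).
#'
#' @param cfg named list as produced inside [bayesian_optimize].
#' @param modalities character subset of `c("year", "genomic", "ndvi")`.
#' @param seed training seed passed through to the network.
#' @return an [mmdl_config].
#' @export
as_mmdl_config <- function(cfg, modalities = c("year", "genomic", "ndvi"),
                           seed = NULL) {
  slots <- list(year = c("nHL1", "N1_1"), genomic = c("nHL2", "N1_2"),
                ndvi = c("nHL3", "N1_3"))
  towers <- list()
  for (q in modalities) {
    towers[[q]] <- list(nHL = cfg[[slots[[q]][1]]], N1 = cfg[[slots[[q]][2]]])
  }
  mmdl_config(towers = towers, lambda = cfg$lambda, dropout = cfg$DO,
              lr = exp(cfg$llr), wd = exp(cfg$lwd), patience = cfg$Pat,
              seed = seed)
}

#' Write a tuning result to disk
#'
#' @param res a `tune_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tune <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(iteration = seq_len(nrow(res$trace)), res$trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  jsonlite::write_json(res$best_config, file.path(dir, "best_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
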