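# Linear epsilon-insensitive support vector regression, solved in the dual
# by sequential minimal optimization (maximal-violating-pair working-set
# selection).  The intercept is the Lagrange multiplier of the equality
# constraint and is not regularized; the coefficient vector is recovered as
# beta = X' theta with theta = alpha_plus - alpha_minus.

#' Settings for support vector regression
#'
#' Defaults are the reference settings of the linear-kernel analysis:
#' tube width `epsilon = 0.1`, cost `C = 1`, tolerance 0.01.
#'
#' @param epsilon insensitive-tube half width (>= 0).
#' @param C cost of constraint violations (> 0).
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter cap on pairwise updates.
#' @return list of class `svr_spec`.
#' @export
svr_spec <- function(epsilon = 0.1, C = 1, tol = 0.01, max_iter = 5e6) {
  stopifnot(epsilon >= 0, C > 0, tol > 0, max_iter >= 1)
  structure(list(epsilon = epsilon, C = C, tol = tol,
                 max_iter = as.integer(max_iter)), class = "svr_spec")
}

#' Fit linear epsilon-insensitive support vector regression
#'
#' Solves `min 0.5 ||beta||^2 + C sum_i V_eps(y_i - beta0 - x_i' beta)` where
#' `V_eps` is the epsilon-insensitive hinge, via its dual with box
#' constraints `[0, C]` and the sum-to-zero equality constraint.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param spec an [svr_spec].
#' @return object of class `svr_fit` with `beta0` (intercept), `beta`
#'   (coefficients), dual variables `theta`, the final KKT violation and the
#'   dual objective value.
#' @export
fit_svr_linear <- function(X, y, spec = svr_spec()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  K <- tcrossprod(X)
  eps <- spec$epsilon; C <- spec$C

  sol <- .svr_smo_cpp(K, y, eps, C, spec$tol, spec$max_iter)
  if (sol$violation >= spec$tol && sol$iterations >= spec$max_iter) {
    stop_mmgp("SVR did not converge in %d updates (KKT violation %.3g)",
              spec$max_iter, sol$violation)
  }
  z <- sol$z
  iter <- sol$iterations
  viol <- sol$violation

  ss <- c(rep(1, n), rep(-1, n))    # +1: alpha_plus, -1: alpha_minus
  theta <- z[seq_len(n)] - z[n + seq_len(n)]
  G <- ss * as.vector(K %*% theta)[c(seq_len(n), seq_len(n))] + eps - ss * y
  msG <- -ss * G
  up <- (ss > 0 & z < C - 1e-12) | (ss < 0 & z > 1e-12)
  low <- (ss < 0 & z < C - 1e-12) | (ss > 0 & z > 1e-12)
  m_up <- if (any(up)) max(msG[up]) else NA_real_
  m_low <- if (any(low)) min(msG[low]) else NA_real_
  beta0 <- mean(c(m_up, m_low), na.rm = TRUE)
  if (!is.finite(beta0)) beta0 <- mean(y)
  beta <- as.vector(crossprod(X, theta))
  dual_obj <- 0.5 * sum(theta * (K %*% theta)) + eps * sum(z) - sum(y * theta)

  structure(list(beta0 = beta0, beta = beta, theta = theta,
                 iterations = iter, kkt_violation = max(viol, 0),
                 dual_objective = dual_obj, spec = spec),
            class = "svr_fit")
}

#' Predict from a fitted support vector regression
#'
#' @param fit an `svr_fit`.
#' @param X feature matrix.
#' @return `beta0 + X %*% beta`.
#' @export
predict_svr <- function(fit, X) {
  as.vector(as.matrix(X) %*% fit$beta + fit$beta0)
}

#' Primal objective of linear epsilon-insensitive SVR
#'
#' `0.5 ||beta||^2 + C sum_i max(|y_i - beta0 - x_i' beta| - epsilon, 0)`.
#' Exposed so solutions can be compared against independent solvers.
#'
#' @param X,y data.
#' @param beta0,beta candidate solution.
#' @param spec an [svr_spec].
#' @return scalar objective value.
#' @export
svr_objective <- function(X, y, beta0, beta, spec = svr_spec()) {
  r <- abs(y - beta0 - as.vector(as.matrix(X) %*% beta))
  0.5 * sum(beta^2) + spec$C * sum(pmax(r - spec$epsilon, 0))
}
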