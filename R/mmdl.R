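# Multimodal residual multilayer perceptron.
#
# One tower per input modality (year design, genomic inputs Z_L L', NDVI
# covariates).  Consecutive hidden layers pair up into residual blocks
# (dense+BN+relu -> dense+BN, skip-add of the block input with a bias-free
# linear projection when widths differ, relu, dropout); an odd trailing layer
# is a plain dense+BN+relu+dropout.  Tower outputs are concatenated into a
# single linear output neuron with L2 on its weights.  The whole engine
# (forward, backprop, Adam, batch normalization, dropout) is implemented here
# in base R so the model is fully inspectable and deterministic given a seed.

#' Hidden-layer widths of one tower
#'
#' Widths halve layer by layer: `N_l = max(1, floor(N1 / 2^(l-1)))`.
#'
#' @param N1 width of the first hidden layer (>= 1).
#' @param nHL number of hidden layers (>= 1).
#' @return integer vector of length `nHL`.
#' @export
layer_widths <- function(N1, nHL) {
  stopifnot(N1 >= 1, nHL >= 1)
  pmax(1L, as.integer(floor(N1 / 2^(seq_len(nHL) - 1))))
}

#' Configuration of the multimodal network
#'
#' @param towers named list (names are modality labels, e.g. `year`,
#'   `genomic`, `ndvi`); each element a list with `nHL` (hidden-layer count)
#'   and `N1` (first-hidden-layer width).
#' @param lambda L2 coefficient shared by all dense layers and the output.
#' @param dropout dropout rate in `[0, 1)` shared by all hidden layers.
#' @param lr initial learning rate; the rate at epoch `t` (0-based) is
#'   `lr * exp(-wd * t)`.
#' @param wd exponential learning-decay rate.
#' @param patience early-stopping patience on the training loss.
#' @param batch_size minibatch size (default 32).
#' @param max_epochs hard epoch cap (default 128).
#' @param val_split fraction of rows held out for the validation loss
#'   (default 0.10; the final rows are held out).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return list of class `mmdl_config`.
#' @export
mmdl_config <- function(towers = list(year = list(nHL = 1, N1 = 8),
                                      genomic = list(nHL = 2, N1 = 64),
                                      ndvi = list(nHL = 1, N1 = 8)),
                        lambda = 1e-4, dropout = 0, lr = 0.01, wd = 0.01,
                        patience = 16, batch_size = 32, max_epochs = 128,
                        val_split = 0.10, seed = NULL) {
  stopifnot(length(towers) >= 1, !is.null(names(towers)),
            dropout >= 0, dropout < 1, lambda >= 0, lr > 0, wd >= 0,
            patience >= 0, batch_size >= 1, max_epochs >= 1,
            val_split >= 0, val_split < 1)
  for (tw in towers) stopifnot(tw$nHL >= 1, tw$N1 >= 1)
  structure(list(towers = towers, lambda = lambda, dropout = dropout,
                 lr = lr, wd = wd, patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_split = val_split, seed = seed),
            class = "mmdl_config")
}

bn_eps <- 1e-3
bn_momentum <- 0.9

#' Build an untrained multimodal network
#'
#' @param input_dims named integer vector/list of input widths, one per
#'   modality; names must appear in `config$towers`.  Dropping a modality
#'   (e.g. the year tower under leave-one-year-out) just omits its name.
#' @param config an [mmdl_config].
#' @return object of class `mmdl_model` with elements `arch`, `params`
#'   (trainable weights), `state` (batch-norm running statistics), `config`.
#' @export
build_mmdl <- function(input_dims, config) {
  mods <- names(input_dims)
  if (length(mods) == 0L) stop_mmgp("empty modality set")
  if (!all(mods %in% names(config$towers))) {
    stop_mmgp("no tower configured for modality: %s",
              paste(setdiff(mods, names(config$towers)), collapse = ", "))
  }
  arch <- list(modalities = mods, towers = list(), fused_dim = 0L)
  for (q in mods) {
    d_in <- as.integer(input_dims[[q]])
    if (d_in < 1L) stop_mmgp("input dim for '%s' must be >= 1", q)
    widths <- layer_widths(config$towers[[q]]$N1, config$towers[[q]]$nHL)
    units <- list()
    l <- 1L
    cur <- d_in
    while (l <= length(widths)) {
      if (l + 1L <= length(widths)) {
        units[[length(units) + 1L]] <-
          list(type = "res", d_in = cur, h1 = widths[l], h2 = widths[l + 1L],
               proj = cur != widths[l + 1L])
        cur <- widths[l + 1L]
        l <- l + 2L
      } else {
        units[[length(units) + 1L]] <-
          list(type = "plain", d_in = cur, h = widths[l])
        cur <- widths[l]
        l <- l + 1L
      }
    }
    arch$towers[[q]] <- list(d_in = d_in, units = units, d_out = cur)
    arch$fused_dim <- arch$fused_dim + cur
  }

  init <- init_mmdl_params(arch, config$seed)
  structure(list(arch = arch, params = init$params, state = init$state,
                 config = config, input_dims = input_dims, history = NULL),
            class = "mmdl_model")
}

# He-normal initialization for relu layers; BN scale 1, shift 0, running
# mean 0 / variance 1.
init_mmdl_params <- function(arch, seed) {
  he <- function(d_in, d_out) {
    matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
  }
  with_seed(seed, {
    params <- list(towers = list(), fusion = NULL)
    state <- list(towers = list())
    for (q in arch$modalities) {
      tw <- arch$towers[[q]]
      pu <- list(); su <- list()
      for (u in tw$units) {
        if (u$type == "res") {
          p <- list(W1 = he(u$d_in, u$h1), b1 = rep(0, u$h1),
                    gm1 = rep(1, u$h1), bt1 = rep(0, u$h1),
                    W2 = he(u$h1, u$h2), b2 = rep(0, u$h2),
                    gm2 = rep(1, u$h2), bt2 = rep(0, u$h2))
          if (u$proj) p$P <- he(u$d_in, u$h2)
          s <- list(rm1 = rep(0, u$h1), rv1 = rep(1, u$h1),
                    rm2 = rep(0, u$h2), rv2 = rep(1, u$h2))
        } else {
          p <- list(W = he(u$d_in, u$h), b = rep(0, u$h),
                    gm = rep(1, u$h), bt = rep(0, u$h))
          s <- list(rm = rep(0, u$h), rv = rep(1, u$h))
        }
        pu[[length(pu) + 1L]] <- p
        su[[length(su) + 1L]] <- s
      }
      params$towers[[q]] <- pu
      state$towers[[q]] <- su
    }
    params$fusion <- list(W = he(arch$fused_dim, 1L), b = 0)
    list(params = params, state = state)
  })
}

#' Number of trainable parameters
#'
#' @param model an `mmdl_model`.
#' @return integer count over dense weights, biases, batch-norm scale/shift
#'   and the fusion layer.
#' @export
mmdl_count_params <- function(model) {
  n <- 0L
  count_rec <- function(x) {
    if (is.list(x)) for (el in x) count_rec(el) else n <<- n + length(x)
  }
  count_rec(model$params)
  n
}

add_bias <- function(z, b) sweep(z, 2L, b, "+")

bn_forward <- function(z, gm, bt, rm, rv, training) {
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2L, mu, "-")^2)
    inv_std <- 1 / sqrt(v + bn_eps)
    zhat <- sweep(sweep(z, 2L, mu, "-"), 2L, inv_std, "*")
    out <- add_bias(sweep(zhat, 2L, gm, "*"), bt)
    list(out = out, cache = list(zhat = zhat, inv_std = inv_std),
         rm = bn_momentum * rm + (1 - bn_momentum) * mu,
         rv = bn_momentum * rv + (1 - bn_momentum) * v)
  } else {
    zhat <- sweep(sweep(z, 2L, rm, "-"), 2L, 1 / sqrt(rv + bn_eps), "*")
    list(out = add_bias(sweep(zhat, 2L, gm, "*"), bt), cache = NULL,
         rm = rm, rv = rv)
  }
}

bn_backward <- function(dout, cache, gm) {
  n <- nrow(dout)
  dzhat <- sweep(dout, 2L, gm, "*")
  dgm <- colSums(dout * cache$zhat)
  dbt <- colSums(dout)
  s1 <- colSums(dzhat) / n
  s2 <- colSums(dzhat * cache$zhat) / n
  dz <- sweep(dzhat - matrix(s1, n, length(s1), byrow = TRUE) -
                cache$zhat * matrix(s2, n, length(s2), byrow = TRUE),
              2L, cache$inv_std, "*")
  list(dz = dz, dgm = dgm, dbt = dbt)
}

drop_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

unit_forward <- function(x, u, p, s, rate, training) {
  if (u$type == "res") {
    z1 <- add_bias(x %*% p$W1, p$b1)
    bn1 <- bn_forward(z1, p$gm1, p$bt1, s$rm1, s$rv1, training)
    a1 <- pmax(bn1$out, 0)
    z2 <- add_bias(a1 %*% p$W2, p$b2)
    bn2 <- bn_forward(z2, p$gm2, p$bt2, s$rm2, s$rv2, training)
    skip <- if (u$proj) x %*% p$P else x
    y0 <- bn2$out + skip
    a2 <- pmax(y0, 0)
    dr <- drop_forward(a2, rate, training)
    list(out = dr$out,
         cache = list(x = x, bn1 = bn1$cache, bn1_out = bn1$out, a1 = a1,
                      bn2 = bn2$cache, y0 = y0, mask = dr$mask),
         state = list(rm1 = bn1$rm, rv1 = bn1$rv, rm2 = bn2$rm, rv2 = bn2$rv))
  } else {
    z <- add_bias(x %*% p$W, p$b)
    bn <- bn_forward(z, p$gm, p$bt, s$rm, s$rv, training)
    a <- pmax(bn$out, 0)
    dr <- drop_forward(a, rate, training)
    list(out = dr$out,
         cache = list(x = x, bn = bn$cache, bn_out = bn$out, mask = dr$mask),
         state = list(rm = bn$rm, rv = bn$rv))
  }
}

unit_backward <- function(dout, u, p, cache, rate) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  if (u$type == "res") {
    dy0 <- dout * (cache$y0 > 0)
    bb2 <- bn_backward(dy0, cache$bn2, p$gm2)
    dW2 <- crossprod(cache$a1, bb2$dz)
    db2 <- colSums(bb2$dz)
    da1 <- bb2$dz %*% t(p$W2)
    dbn1 <- da1 * (cache$bn1_out > 0)
    bb1 <- bn_backward(dbn1, cache$bn1, p$gm1)
    dW1 <- crossprod(cache$x, bb1$dz)
    db1 <- colSums(bb1$dz)
    dx <- bb1$dz %*% t(p$W1)
    grads <- list(W1 = dW1, b1 = db1, gm1 = bb1$dgm, bt1 = bb1$dbt,
                  W2 = dW2, b2 = db2, gm2 = bb2$dgm, bt2 = bb2$dbt)
    if (u$proj) {
      grads$P <- crossprod(cache$x, dy0)
      dx <- dx + dy0 %*% t(p$P)
    } else {
      dx <- dx + dy0
    }
    list(dx = dx, grads = grads)
  } else {
    dbn <- dout * (cache$bn_out > 0)
    bb <- bn_backward(dbn, cache$bn, p$gm)
    list(dx = bb$dz %*% t(p$W),
         grads = list(W = crossprod(cache$x, bb$dz), b = colSums(bb$dz),
                      gm = bb$dgm, bt = bb$dbt))
  }
}

mmdl_forward <- function(model, inputs, training = FALSE) {
  arch <- model$arch
  rate <- model$config$dropout
  caches <- list()
  outs <- list()
  state <- model$state
  for (q in arch$modalities) {
    x <- inputs[[q]]
    if (is.null(x)) stop_mmgp("missing input for modality '%s'", q)
    if (ncol(x) != arch$towers[[q]]$d_in) {
      stop_mmgp("modality '%s': expected %d columns, got %d",
                q, arch$towers[[q]]$d_in, ncol(x))
    }
    ucaches <- list()
    for (i in seq_along(arch$towers[[q]]$units)) {
      u <- arch$towers[[q]]$units[[i]]
      fw <- unit_forward(x, u, model$params$towers[[q]][[i]],
                         state$towers[[q]][[i]], rate, training)
      x <- fw$out
      ucaches[[i]] <- fw$cache
      state$towers[[q]][[i]] <- fw$state
    }
    outs[[q]] <- x
    caches[[q]] <- ucaches
  }
  H <- do.call(cbind, outs)
  yhat <- as.vector(H %*% model$params$fusion$W + model$params$fusion$b)
  list(yhat = yhat, H = H, caches = caches, state = state)
}

mmdl_backward <- function(model, inputs, fw, y) {
  arch <- model$arch
  n <- length(y)
  lam <- model$config$lambda
  dyhat <- 2 * (fw$yhat - y) / n
  grads <- list(towers = list(),
                fusion = list(W = crossprod(fw$H, dyhat) + 2 * lam * model$params$fusion$W,
                              b = sum(dyhat)))
  dH <- dyhat %*% t(model$params$fusion$W)
  off <- 0L
  for (q in arch$modalities) {
    d_out <- arch$towers[[q]]$d_out
    dx <- dH[, off + seq_len(d_out), drop = FALSE]
    off <- off + d_out
    units <- arch$towers[[q]]$units
    tg <- vector("list", length(units))
    for (i in rev(seq_along(units))) {
      bw <- unit_backward(dx, units[[i]], model$params$towers[[q]][[i]],
                          fw$caches[[q]][[i]], model$config$dropout)
      dx <- bw$dx
      g <- bw$grads
      # L2 applies to the dense weight matrices (incl. projections)
      for (nm in intersect(names(g), c("W", "W1", "W2", "P"))) {
        g[[nm]] <- g[[nm]] + 2 * lam * model$params$towers[[q]][[i]][[nm]]
      }
      tg[[i]] <- g
    }
    grads$towers[[q]] <- tg
  }
  grads
}

mmdl_l2_penalty <- function(model) {
  lam <- model$config$lambda
  if (lam <= 0) return(0)
  tot <- 0
  for (q in model$arch$modalities) {
    for (p in model$params$towers[[q]]) {
      for (nm in intersect(names(p), c("W", "W1", "W2", "P"))) {
        tot <- tot + sum(p[[nm]]^2)
      }
    }
  }
  lam * (tot + sum(model$params$fusion$W^2))
}

# Recursive Adam step over the nested parameter structure.
adam_step <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(params)) {
    for (nm in names(params) %||% seq_along(params)) {
      res <- adam_step(params[[nm]], grads[[nm]], m[[nm]], v[[nm]], lr, t,
                       beta1, beta2, eps)
      params[[nm]] <- res$params; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    list(params = params, m = m, v = v)
  } else {
    g <- as.numeric(grads)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    upd <- lr * mh / (sqrt(vh) + eps)
    if (!is.null(dim(params))) dim(upd) <- dim(params)
    list(params = params - upd, m = m, v = v)
  }
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

#' Train the multimodal network
#'
#' Minimizes mean squared error plus the L2 penalties with Adam.  The
#' learning rate at epoch `t` (0-based) is `lr * exp(-wd * t)`.  The final
#' `val_split` fraction of rows is held out to report a validation loss (the
#' tuning objective); training rows are shuffled into minibatches each epoch.
#' Training stops once the epoch training loss has failed to improve for
#' `patience` consecutive epochs, or at `max_epochs`.
#'
#' @param model a [build_mmdl] result.
#' @param inputs named list of modality matrices, row-aligned with `y`.
#' @param y numeric response vector.
#' @return The trained model; `model$history` holds per-epoch `lr`,
#'   `train_loss` and `val_loss`, and `model$stopped_epoch` the epoch count.
#' @export
train_mmdl <- function(model, inputs, y) {
  cfg <- model$config
  n <- length(y)
  for (q in model$arch$modalities) {
    if (nrow(inputs[[q]]) != n) stop_mmgp("modality '%s' not row-aligned", q)
  }
  n_val <- floor(cfg$val_split * n)
  val_idx <- if (n_val > 0) seq.int(n - n_val + 1L, n) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  m_state <- zero_like(model$params)
  v_state <- zero_like(model$params)
  best <- Inf; wait <- 0L; step <- 0L
  hist <- list()

  with_seed(derive_seed(cfg$seed, 1L) %||% NULL, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr_e <- cfg$lr * exp(-cfg$wd * (epoch - 1))
      ord <- sample(tr_idx)
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      ends <- c(starts[-1L] - 1L, length(ord))
      # fold a trailing singleton into the previous batch (batch norm
      # statistics need at least 2 rows)
      if (length(starts) > 1L && ends[length(ends)] == starts[length(starts)]) {
        starts <- starts[-length(starts)]
        ends <- ends[-length(ends)]
        ends[length(ends)] <- length(ord)
      }
      batch_losses <- numeric(0)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:ends[bi]]
        xb <- lapply(inputs, function(m) m[idx, , drop = FALSE])
        fw <- mmdl_forward(model, xb, training = TRUE)
        model$state <- fw$state
        loss <- mean((fw$yhat - y[idx])^2) + mmdl_l2_penalty(model)
        if (!is.finite(loss)) stop_mmgp("non-finite loss at epoch %d", epoch)
        grads <- mmdl_backward(model, xb, fw, y[idx])
        step <- step + 1L
        upd <- adam_step(model$params, grads, m_state, v_state, lr_e, step)
        model$params <- upd$params; m_state <- upd$m; v_state <- upd$v
        batch_losses <- c(batch_losses, loss)
      }
      train_loss <- mean(batch_losses)
      val_loss <- NA_real_
      if (length(val_idx)) {
        xv <- lapply(inputs, function(m) m[val_idx, , drop = FALSE])
        pv <- mmdl_forward(model, xv, training = FALSE)$yhat
        val_loss <- mean((pv - y[val_idx])^2)
      }
      hist[[epoch]] <- c(epoch = epoch, lr = lr_e,
                         train_loss = train_loss, val_loss = val_loss)
      if (train_loss < best) {
        best <- train_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= max(cfg$patience, 1L)) break
      }
    }
  })

  model$history <- as.data.frame(do.call(rbind, hist))
  model$stopped_epoch <- nrow(model$history)
  model$val_loss <- {
    vl <- model$history$val_loss
    if (all(is.na(vl))) NA_real_ else vl[length(vl)]
  }
  model
}

#' Predict with a multimodal network
#'
#' Deterministic forward pass: dropout off, batch normalization in inference
#' mode (running statistics).
#'
#' @param model an `mmdl_model`.
#' @param inputs named list of modality matrices.
#' @return numeric vector of predictions.
#' @export
predict_mmdl <- function(model, inputs) {
  mmdl_forward(model, inputs, training = FALSE)$yhat
}

#' Write a trained network to disk
#'
#' Config as JSON, training history as CSV, weights as a flat JSON of arrays.
#'
#' @param model an `mmdl_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_mmdl <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "seed")],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(model$params, file.path(dir, "weights.json"),
                       digits = NA)
  invisible(dir)
}
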