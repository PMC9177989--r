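# Minimal dense-network core: affine, batch-normalisation, ELU and dropout
# layers with exact backpropagation, plus an Adam optimiser. Everything is
# plain double-precision matrix algebra (rows = samples), which is all the
# adversarial model needs and keeps training fully deterministic under R's
# RNG.
#
# Conventions:
#   * a network is a list of layer lists, each with a $type field;
#   * nn_forward() returns the output, per-layer caches for the backward
#     pass, and the (possibly updated) network, because batch-norm layers
#     carry running statistics;
#   * frozen networks are forward-passed with update_stats = FALSE so their
#     parameters AND buffers are bitwise unchanged by a training step.

glorot_uniform <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

nn_dense <- function(n_in, n_out) {
  list(type = "dense", W = glorot_uniform(n_in, n_out), b = rep(0, n_out))
}

# Batch statistics in training mode, exponentially-smoothed running
# statistics (decay `momentum`) in inference mode. eps stabilises the
# variance; population (1/N) variance is used for the batch statistics.
nn_batchnorm <- function(n, momentum = 0.9, eps = 1e-3) {
  list(type = "bn", gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n),
       momentum = momentum, eps = eps)
}

nn_elu <- function(alpha = 1) list(type = "elu", alpha = alpha)

nn_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate)

# Forward pass. training switches batch-norm to batch statistics and
# activates dropout; update_stats additionally refreshes the running
# statistics (set FALSE when the network is frozen).
#
# `X` is samples x features at the interface; internally the batch is held
# feature-major (features x batch) so per-feature vectors (bias, batch-norm
# statistics) broadcast through R's native column recycling without any
# rep() expansion — this is the hot path of training.
nn_forward <- function(net, X, training = FALSE, update_stats = training) {
  caches <- vector("list", length(net))
  T <- t(X)
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(T = T)
      T <- crossprod(l$W, T) + l$b
    } else if (l$type == "bn") {
      if (training) {
        nc <- ncol(T)
        mu <- .rowMeans(T, nrow(T), nc)
        centred <- T - mu
        v <- .rowMeans(centred^2, nrow(T), nc)
        inv_std <- 1 / sqrt(v + l$eps)
        xhat <- centred * inv_std
        if (update_stats) {
          l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
          l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
          net[[i]] <- l
        }
        caches[[i]] <- list(xhat = xhat, inv_std = inv_std)
        T <- xhat * l$gamma + l$beta
      } else {
        inv_std <- 1 / sqrt(l$run_var + l$eps)
        T <- (T - l$run_mean) * (inv_std * l$gamma) + l$beta
        caches[[i]] <- list(inference = TRUE)
      }
    } else if (l$type == "elu") {
      neg <- T < 0
      out <- T
      out[neg] <- l$alpha * expm1(T[neg])
      caches[[i]] <- list(neg = neg, out = out)
      T <- out
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(stats::runif(length(T)), nrow(T)) >= l$rate) /
          (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        T <- T * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else {
      stop("unknown layer type: ", l$type)
    }
  }
  list(out = t(T), caches = caches, net = net)
}

# Backward pass through a training-mode forward. Returns the gradient with
# respect to the input and (if want_grads) per-layer parameter gradients.
# Gradients are exchanged samples x features at the interface and held
# feature-major internally, mirroring nn_forward().
nn_backward <- function(net, caches, dOut, want_grads = TRUE) {
  grads <- vector("list", length(net))
  G <- t(dOut)
  for (i in rev(seq_along(net))) {
    l <- net[[i]]
    cache <- caches[[i]]
    if (l$type == "dense") {
      if (want_grads) {
        grads[[i]] <- list(W = tcrossprod(cache$T, G),
                           b = .rowSums(G, nrow(G), ncol(G)))
      }
      G <- l$W %*% G
    } else if (l$type == "bn") {
      if (!is.null(cache$inference)) {
        stop("cannot backpropagate through an inference-mode forward")
      }
      xhat <- cache$xhat
      nr <- nrow(G)
      nc <- ncol(G)
      if (want_grads) {
        grads[[i]] <- list(gamma = .rowSums(G * xhat, nr, nc),
                           beta = .rowSums(G, nr, nc))
      }
      dxhat <- G * l$gamma
      m1 <- .rowMeans(dxhat, nr, nc)
      m2 <- .rowMeans(dxhat * xhat, nr, nc)
      G <- (dxhat - m1 - xhat * m2) * cache$inv_std
    } else if (l$type == "elu") {
      neg <- cache$neg
      G[neg] <- G[neg] * (cache$out[neg] + l$alpha)
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) G <- G * cache$mask
    }
  }
  list(dX = t(G), grads = grads)
}

nn_param_names <- function(layer) {
  switch(layer$type, dense = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

# List of parameter tensors plus batch-norm buffers; used for hashing and
# freeze-contract checks.
nn_state <- function(net) {
  lapply(net, function(l) {
    keep <- c(nn_param_names(l), if (l$type == "bn") c("run_mean", "run_var"))
    l[keep]
  })
}

adam_init <- function(net) {
  list(t = 0L, m = lapply(net, function(l) {
    lapply(l[nn_param_names(l)], function(p) p * 0)
  }), v = lapply(net, function(l) {
    lapply(l[nn_param_names(l)], function(p) p * 0)
  }))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(net)) {
    pn <- nn_param_names(net[[i]])
    if (!length(pn) || is.null(grads[[i]])) next
    for (p in pn) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[p]] / corr1
      vhat <- state$v[[i]][[p]] / corr2
      net[[i]][[p]] <- net[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
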