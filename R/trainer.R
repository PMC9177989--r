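#' Training configuration
#'
#' Collects the optimisation knobs of the adversarial deconvolution model.
#' Defaults follow the reference setting for Visium-scale data: 3000
#' alternating iterations at minibatch size 512, domain-classifier learning
#' rate 0.005, adversarial weight alpha 0.6 (use 1.0 for the lung-style
#' 1:1 weighting). The main-model learning rate (embedder + source
#' classifier, Adam) defaults to 0.001.
#'
#' @param iterations alternating adversarial iterations.
#' @param batch_size minibatch size (applied to pseudospots and real spots
#'   alike; real spots are resampled with replacement when fewer exist).
#' @param lr_main Adam learning rate for the embedder and source classifier.
#' @param lr_domain Adam learning rate for the domain classifier.
#' @param alpha adversarial loss weight in `L_total = L_s + alpha * L_adv1`.
#' @param pretrain_epochs epochs of source-only pretraining.
#' @param seed master seed for minibatch sampling and dropout.
#' @return A list of class `training_config`.
#' @export
training_config <- function(iterations = 3000L, batch_size = 512L,
                            lr_main = 0.001, lr_domain = 0.005,
                            alpha = 0.6, pretrain_epochs = 10L, seed = 0L) {
  assert_scalar_number(iterations, "iterations", positive = TRUE,
                       integerish = TRUE)
  assert_scalar_number(batch_size, "batch_size", positive = TRUE,
                       integerish = TRUE)
  assert_scalar_number(lr_main, "lr_main", positive = TRUE)
  assert_scalar_number(lr_domain, "lr_domain", positive = TRUE)
  if (pretrain_epochs < 0) stop("pretrain_epochs must be >= 0", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 lr_main = lr_main, lr_domain = lr_domain, alpha = alpha,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

check_batch_for_training <- function(batch) {
  stopifnot(inherits(batch, "pseudospot_batch"))
  if (batch$layer != "scaled01") {
    stop("pseudospot batch must be min-max scaled (scaled01) before training",
         call. = FALSE)
  }
  if (max(abs(rowSums(batch$Y) - 1)) > 1e-6) {
    stop("pseudospot fraction rows must sum to 1", call. = FALSE)
  }
  invisible(batch)
}

abort_on_nan <- function(loss, stage, iter) {
  if (!is.finite(loss)) {
    stop(sprintf("non-finite loss (%s) at %s step %d; try a lower learning rate",
                 format(loss), stage, iter), call. = FALSE)
  }
  loss
}

# One gradient step of f+S on L_s for a pseudospot minibatch.
source_step <- function(model, Xb, Yb, lr) {
  ff <- nn_forward(model$f, Xb, training = TRUE)
  model$f <- ff$net
  sf <- nn_forward(model$S, ff$out, training = TRUE)
  model$S <- sf$net
  P <- softmax_rows(sf$out)
  loss <- kld_source_loss(Yb, P)
  dlogits <- (P - Yb) / nrow(Xb)
  bs <- nn_backward(model$S, sf$caches, dlogits)
  bf <- nn_backward(model$f, ff$caches, bs$dX)
  up <- adam_step(model$S, bs$grads, model$opt$main$S, lr)
  model$S <- up$net
  model$opt$main$S <- up$state
  up <- adam_step(model$f, bf$grads, model$opt$main$f, lr)
  model$f <- up$net
  model$opt$main$f <- up$state
  list(model = model, loss = loss)
}

#' Pretrain the source model on pseudospots
#'
#' Minimises the Kullback-Leibler source loss alone by minibatch Adam over
#' the pseudospot set, updating the feature embedder and source classifier;
#' the domain classifier is untouched. This initialises the weights before
#' the adversarial phases, and on its own constitutes the
#' no-domain-adaptation baseline (see [train_nn_wo_da()]).
#'
#' @param model an [init_model()] state.
#' @param batch a scaled [generate_pseudospots()] batch.
#' @param cfg a [training_config()].
#' @return The updated model; per-epoch losses in `model$history$pretrain_loss`.
#' @export
pretrain_source <- function(model, batch, cfg = training_config()) {
  stopifnot(inherits(model, "adda_model"))
  check_batch_for_training(batch)
  if (ncol(batch$X) != model$n_genes || ncol(batch$Y) != model$n_types) {
    stop("pseudospot batch does not match model dimensions", call. = FALSE)
  }
  if (cfg$pretrain_epochs == 0L) return(model)
  if (is.null(model$opt$main)) model$opt$main <- list()
  model$opt$main$f <- model$opt$main$f %||% adam_init(model$f)
  model$opt$main$S <- model$opt$main$S %||% adam_init(model$S)

  n <- nrow(batch$X)
  bs <- min(cfg$batch_size, n)
  with_seed(cfg$seed, {
    losses <- numeric(cfg$pretrain_epochs)
    for (ep in seq_len(cfg$pretrain_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        st <- source_step(model, batch$X[idx, , drop = FALSE],
                          batch$Y[idx, , drop = FALSE], cfg$lr_main)
        model <- st$model
        ep_loss <- ep_loss + st$loss * length(idx)
        abort_on_nan(st$loss, "pretraining", ep)
      }
      losses[ep] <- ep_loss / n
    }
    model$history$pretrain_loss <- c(model$history$pretrain_loss, losses)
  })
  model
}

#' Adversarial domain adaptation training
#'
#' Runs the two-phase alternating optimisation for `cfg$iterations`
#' iterations. Each iteration samples a pseudospot minibatch and an
#' equal-size real-spot minibatch, then:
#' \describe{
#'   \item{phase A}{updates the embedder and source classifier to minimise
#'     `L_s + alpha * L_adv1` with the domain classifier frozen (its
#'     parameters and batch-norm buffers receive no update; gradients flow
#'     through it into the embedder);}
#'   \item{phase B}{updates the domain classifier to minimise `L_adv2`
#'     (real = 1, pseudospot = 0) at `lr_domain`, with the embedder and
#'     source classifier frozen.}
#' }
#' For the adversarial forward the two domains are concatenated into one
#' batch so the embedder's batch normalisation sees both. Loss curves for
#' `L_s`, `L_adv1` and `L_adv2` are recorded per iteration in
#' `model$history`.
#'
#' @param model a pretrained `adda_model`.
#' @param pseudo a scaled pseudospot batch (source domain).
#' @param spots a [count_matrix()] with `layer = "scaled01"`, same gene
#'   panel and order as the pseudospots (target domain).
#' @param cfg a [training_config()]; `cfg$alpha` overrides `model$alpha`.
#' @param check_freeze assert the freeze contracts (parameter hashes of the
#'   frozen components unchanged) at every iteration; for testing.
#' @return The updated model.
#' @export
adversarial_train <- function(model, pseudo, spots, cfg = training_config(),
                              check_freeze = FALSE) {
  stopifnot(inherits(model, "adda_model"), inherits(spots, "count_matrix"))
  check_batch_for_training(pseudo)
  if (spots$layer != "scaled01") {
    stop("real spots must be min-max scaled (scaled01) before training",
         call. = FALSE)
  }
  if (!identical(pseudo$gene_ids, spots$gene_ids)) {
    stop("pseudospots and spots must share the same gene panel and order",
         call. = FALSE)
  }
  alpha <- cfg$alpha %||% model$alpha
  model$alpha <- alpha
  Xr_all <- t(spots$values)  # spots x genes
  n_p <- nrow(pseudo$X)
  n_r <- nrow(Xr_all)
  bs <- min(cfg$batch_size, n_p)

  model$opt$main <- model$opt$main %||% list()
  model$opt$main$f <- model$opt$main$f %||% adam_init(model$f)
  model$opt$main$S <- model$opt$main$S %||% adam_init(model$S)
  model$opt$domain <- model$opt$domain %||% adam_init(model$D)

  L_s_log <- L_adv1_log <- L_adv2_log <- numeric(cfg$iterations)

  with_seed(cfg$seed + 1L, {
    for (it in seq_len(cfg$iterations)) {
      ip <- sample.int(n_p, bs, replace = n_p < bs)
      ir <- sample.int(n_r, bs, replace = n_r < bs)
      Xp <- pseudo$X[ip, , drop = FALSE]
      Yp <- pseudo$Y[ip, , drop = FALSE]
      Xr <- Xr_all[ir, , drop = FALSE]

      if (check_freeze) {
        h_d <- param_hash(model, "D")
      }

      # ---- phase A: update f, S on L_s + alpha * L_adv1 (D frozen) ----
      ff <- nn_forward(model$f, rbind(Xp, Xr), training = TRUE)
      model$f <- ff$net
      Z <- ff$out
      sf <- nn_forward(model$S, Z[seq_len(bs), , drop = FALSE],
                       training = TRUE)
      model$S <- sf$net
      P <- softmax_rows(sf$out)
      L_s <- kld_source_loss(Yp, P)
      df <- nn_forward(model$D, Z, training = TRUE, update_stats = FALSE)
      d_prob <- sigmoid(df$out)
      # inverted labels: pseudospots (first bs rows) should look real (1),
      # real spots simulated (0)
      L_adv1 <- adv_loss_generator(D_p = d_prob[seq_len(bs)],
                                   D_r = d_prob[bs + seq_len(bs)])
      t_inv <- c(rep(1, bs), rep(0, bs))
      dlogit_d <- matrix((as.vector(d_prob) - t_inv) / bs, ncol = 1L)
      dZ_adv <- nn_backward(model$D, df$caches, dlogit_d,
                            want_grads = FALSE)$dX
      dlogits_s <- (P - Yp) / bs
      bS <- nn_backward(model$S, sf$caches, dlogits_s)
      dZ <- alpha * dZ_adv
      dZ[seq_len(bs), ] <- dZ[seq_len(bs), , drop = FALSE] + bS$dX
      bF <- nn_backward(model$f, ff$caches, dZ)
      up <- adam_step(model$S, bS$grads, model$opt$main$S, cfg$lr_main)
      model$S <- up$net
      model$opt$main$S <- up$state
      up <- adam_step(model$f, bF$grads, model$opt$main$f, cfg$lr_main)
      model$f <- up$net
      model$opt$main$f <- up$state

      if (check_freeze) {
        stopifnot(identical(h_d, param_hash(model, "D")))
        h_f <- param_hash(model, "f")
        h_s <- param_hash(model, "S")
      }

      # ---- phase B: update D on L_adv2 (f, S frozen) ----
      ff2 <- nn_forward(model$f, rbind(Xr, Xp), training = TRUE,
                        update_stats = FALSE)
      df2 <- nn_forward(model$D, ff2$out, training = TRUE)
      model$D <- df2$net
      d_prob2 <- sigmoid(df2$out)
      L_adv2 <- adv_loss_discriminator(D_r = d_prob2[seq_len(bs)],
                                       D_p = d_prob2[bs + seq_len(bs)])
      t_true <- c(rep(1, bs), rep(0, bs))
      dlogit2 <- matrix((as.vector(d_prob2) - t_true) / bs, ncol = 1L)
      bD <- nn_backward(model$D, df2$caches, dlogit2)
      up <- adam_step(model$D, bD$grads, model$opt$domain, cfg$lr_domain)
      model$D <- up$net
      model$opt$domain <- up$state

      if (check_freeze) {
        stopifnot(identical(h_f, param_hash(model, "f")),
                  identical(h_s, param_hash(model, "S")))
      }

      abort_on_nan(L_s, "adversarial (L_s)", it)
      abort_on_nan(L_adv1, "adversarial (L_adv1)", it)
      abort_on_nan(L_adv2, "adversarial (L_adv2)", it)
      L_s_log[it] <- L_s
      L_adv1_log[it] <- L_adv1
      L_adv2_log[it] <- L_adv2
    }
  })
  model$history$L_s <- c(model$history$L_s, L_s_log)
  model$history$L_adv1 <- c(model$history$L_adv1, L_adv1_log)
  model$history$L_adv2 <- c(model$history$L_adv2, L_adv2_log)
  model
}

#' Predict per-spot cell-type fractions
#'
#' Applies the trained model in inference mode (batch-norm running
#' statistics, no dropout), so the prediction for a spot does not depend on
#' which other spots are in the batch.
#'
#' @param model a trained `adda_model`.
#' @param spots a [count_matrix()] with `layer = "scaled01"` on the
#'   training gene panel.
#' @return A [fraction_map()] with one probability row per spot.
#' @export
predict_fractions <- function(model, spots) {
  stopifnot(inherits(model, "adda_model"), inherits(spots, "count_matrix"))
  if (spots$layer != "scaled01") {
    stop("spots must be min-max scaled (scaled01) before prediction",
         call. = FALSE)
  }
  if (nrow(spots$values) != model$n_genes ||
      (!is.null(model$panel) && !identical(spots$gene_ids, model$panel))) {
    stop("spot gene panel does not match the training panel", call. = FALSE)
  }
  P <- model_predict_matrix(model, t(spots$values))
  types <- model$cell_types %||% paste0("type_", seq_len(model$n_types))
  fraction_map(P, spot_ids = spots$sample_ids, cell_types = types)
}

#' Train the no-domain-adaptation baseline
#'
#' Trains the identical embedder + source classifier architecture on
#' pseudospots only, skipping both adversarial phases. The domain
#' classifier remains at initialisation. This is the ablation baseline the
#' adversarial model is compared against.
#'
#' @param pseudo a scaled pseudospot batch.
#' @param cfg a [training_config()].
#' @param model optional pre-initialised model (defaults to
#'   [init_model()] with dimensions from the batch and `seed = cfg$seed`).
#' @return A trained `adda_model`.
#' @export
train_nn_wo_da <- function(pseudo, cfg = training_config(), model = NULL) {
  check_batch_for_training(pseudo)
  if (is.null(model)) {
    model <- init_model(ncol(pseudo$X), ncol(pseudo$Y), alpha = cfg$alpha,
                        seed = cfg$seed)
  }
  model$cell_types <- model$cell_types %||% pseudo$cell_type_order
  model$panel <- model$panel %||% pseudo$gene_ids
  pretrain_source(model, pseudo, cfg)
}

#' Save / load a model checkpoint
#'
#' Single-file versioned checkpoint sufficient for save -> load -> predict
#' equality.
#'
#' @param model an `adda_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "adda_model"))
  saveRDS(list(format = "spotdecon_adda_checkpoint", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spotdecon_adda_checkpoint")) {
    stop("not a spotdecon model checkpoint: ", path, call. = FALSE)
  }
  obj$model
}

#' Tidy the loss history of a trained model
#'
#' @param x an `adda_model`.
#' @param ... unused.
#' @return A tibble with columns `phase`, `step`, `loss`, `metric`.
#' @method tidy adda_model
#' @export
tidy.adda_model <- function(x, ...) {
  h <- x$history
  out <- list()
  if (!is.null(h$pretrain_loss)) {
    out$pre <- tibble::tibble(phase = "pretrain",
                              step = seq_along(h$pretrain_loss),
                              metric = "L_s", loss = h$pretrain_loss)
  }
  for (m in c("L_s", "L_adv1", "L_adv2")) {
    if (!is.null(h[[m]])) {
      out[[m]] <- tibble::tibble(phase = "adversarial",
                                 step = seq_along(h[[m]]),
                                 metric = m, loss = h[[m]])
    }
  }
  dplyr::bind_rows(out)
}

#' One-line summary of a trained model
#'
#' @param x an `adda_model`.
#' @param ... unused.
#' @return A one-row tibble: dimensions, alpha, final losses.
#' @method glance adda_model
#' @export
glance.adda_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_genes = x$n_genes, n_types = x$n_types, alpha = x$alpha,
    pretrain_epochs = length(h$pretrain_loss %||% numeric(0)),
    iterations = length(h$L_s %||% numeric(0)),
    final_L_s = if (length(h$L_s)) h$L_s[length(h$L_s)]
                else if (length(h$pretrain_loss))
                  h$pretrain_loss[length(h$pretrain_loss)] else NA_real_,
    final_L_adv2 = if (length(h$L_adv2)) h$L_adv2[length(h$L_adv2)]
                   else NA_real_
  )
}
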