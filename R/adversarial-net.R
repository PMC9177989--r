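#' Initialise the adversarial deconvolution model
#'
#' The model has three parts sharing one feature embedder:
#' \describe{
#'   \item{f, feature embedder}{two affine stages, gene panel -> 1024 ->
#'     64, each followed by batch normalisation and ELU activation. The
#'     same parameter block feeds both classifier heads.}
#'   \item{S, source classifier}{one affine layer 64 -> K with softmax
#'     output; predicts the cell-type fraction vector and is trained with
#'     the Kullback-Leibler loss [kld_source_loss()].}
#'   \item{D, domain classifier}{affine 64 -> 32 with batch normalisation,
#'     ELU and dropout, then affine 32 -> 1 with sigmoid output: the
#'     probability that the input is a real spatial spot. Trained with
#'     binary cross-entropy ([adv_loss_discriminator()]); the embedder is
#'     trained against it through the inverted-label loss
#'     [adv_loss_generator()] weighted by `alpha`.}
#' }
#' Affine weights are Glorot-uniform with zero biases; batch-norm starts at
#' gamma = 1, beta = 0. Initialisation is reproducible from `seed`.
#'
#' @param n_genes size of the input gene panel.
#' @param n_types number of cell types (K >= 2).
#' @param alpha non-negative weight of the adversarial term in the total
#'   embedder loss `L_total = L_s + alpha * L_adv1`.
#' @param seed integer seed for the parameter draw.
#' @param hidden sizes of the two embedder stages.
#' @param domain_hidden size of the domain classifier's hidden layer.
#' @param dropout_rate dropout rate in the domain classifier.
#' @return An object of class `adda_model`.
#' @export
init_model <- function(n_genes, n_types, alpha = 0.6, seed = 0L,
                       hidden = c(1024L, 64L), domain_hidden = 32L,
                       dropout_rate = 0.5) {
  assert_scalar_number(n_genes, "n_genes", positive = TRUE, integerish = TRUE)
  assert_scalar_number(n_types, "n_types", positive = TRUE, integerish = TRUE)
  if (n_types < 2) stop("need at least 2 cell types", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(length(hidden) == 2L)
  emb_dim <- hidden[2]

  nets <- with_seed(seed, {
    f <- list(nn_dense(n_genes, hidden[1]), nn_batchnorm(hidden[1]),
              nn_elu(), nn_dense(hidden[1], emb_dim), nn_batchnorm(emb_dim),
              nn_elu())
    S <- list(nn_dense(emb_dim, n_types))
    D <- list(nn_dense(emb_dim, domain_hidden), nn_batchnorm(domain_hidden),
              nn_elu(), nn_dropout(dropout_rate),
              nn_dense(domain_hidden, 1L))
    list(f = f, S = S, D = D)
  })

  structure(
    list(f = nets$f, S = nets$S, D = nets$D,
         alpha = alpha, n_genes = as.integer(n_genes),
         n_types = as.integer(n_types), rng_seed = as.integer(seed),
         panel = NULL, cell_types = NULL,
         opt = list(main = NULL, domain = NULL),
         history = NULL),
    class = "adda_model"
  )
}

#' @export
print.adda_model <- function(x, ...) {
  cat(sprintf(
    "<adda_model> %d genes -> 64-d embedding -> %d cell types (alpha = %g)\n",
    x$n_genes, x$n_types, x$alpha))
  if (!is.null(x$history)) {
    cat(sprintf("  trained: %d pretraining epochs, %d adversarial iterations\n",
                length(x$history$pretrain_loss %||% integer(0)),
                length(x$history$L_s %||% integer(0))))
  }
  invisible(x)
}

# Inference-mode embedding + softmax fractions for a samples x genes matrix.
model_predict_matrix <- function(model, X) {
  z <- nn_forward(model$f, X, training = FALSE)$out
  softmax_rows(nn_forward(model$S, z, training = FALSE)$out)
}

#' Hash of a model component's parameters and buffers
#'
#' Used by the freeze-contract checks: a component that is frozen during a
#' training phase must keep an identical hash across the step (parameters
#' and batch-norm running statistics alike).
#'
#' @param model an `adda_model`.
#' @param component `"f"`, `"S"` or `"D"`.
#' @return A character hash.
#' @export
param_hash <- function(model, component = c("f", "S", "D")) {
  component <- match.arg(component)
  rlang::hash(nn_state(model[[component]]))
}

# ---- losses -----------------------------------------------------------

#' Kullback-Leibler source loss
#'
#' Mean over the batch of `sum_k Y_k * log(Y_k / (S_k + eps))`, natural
#' log, with the convention `0 * log(0 / .) = 0`. This is the loss of the
#' source classifier: it vanishes when predicted and true fraction
#' distributions coincide.
#'
#' @param Y true fraction matrix (rows sum to 1).
#' @param S_out predicted fraction matrix (softmax rows).
#' @param eps clipping constant inside the log.
#' @return Non-negative scalar.
#' @export
kld_source_loss <- function(Y, S_out, eps = 1e-8) {
  if (!all(dim(Y) == dim(S_out))) {
    stop("Y and S_out must have identical dimensions", call. = FALSE)
  }
  term <- ifelse(Y > 0, Y * (log(Y) - log(S_out + eps)), 0)
  mean(rowSums(term))
}

#' Inverted-label adversarial loss (embedder side)
#'
#' `mean(-log D_p - log(1 - D_r))` over the batch: the embedder lowers this
#' by making pseudospot embeddings look real and real-spot embeddings look
#' simulated, i.e. by fooling the domain classifier. Added to the source
#' loss with weight alpha: `L_total = L_s + alpha * L_adv1`.
#'
#' @param D_p domain-classifier outputs on pseudospots (probabilities).
#' @param D_r domain-classifier outputs on real spots.
#' @param eps probability clipping inside the logs.
#' @return Non-negative scalar.
#' @export
adv_loss_generator <- function(D_p, D_r, eps = 1e-8) {
  D_p <- clip01(as.vector(D_p), eps)
  D_r <- clip01(as.vector(D_r), eps)
  mean(-log(D_p)) + mean(-log(1 - D_r))
}

#' Domain-classifier loss
#'
#' `mean(-log D_r - log(1 - D_p))`: standard binary cross-entropy for
#' discriminating real spots (label 1) from pseudospots (label 0). The
#' embedder is frozen while this is minimised.
#'
#' @param D_r domain-classifier outputs on real spots (probabilities).
#' @param D_p domain-classifier outputs on pseudospots.
#' @param eps probability clipping inside the logs.
#' @return Non-negative scalar.
#' @export
adv_loss_discriminator <- function(D_r, D_p, eps = 1e-8) {
  adv_loss_generator(D_p = D_r, D_r = D_p, eps = eps)
}
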