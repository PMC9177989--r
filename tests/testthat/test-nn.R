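# The network core is hand-written, so its backward pass is checked against
# central finite differences: this is the ground truth for every gradient
# the trainer uses.

ns <- asNamespace("spotdecon")

test_that("backpropagation matches finite differences through dense/bn/elu", {
  set.seed(1)
  net <- spotdecon:::with_seed(5, list(
    ns$nn_dense(7, 6), ns$nn_batchnorm(6), ns$nn_elu(), ns$nn_dense(6, 3)
  ))
  X <- matrix(rnorm(4 * 7), 4, 7)
  Y <- matrix(runif(4 * 3), 4)
  Y <- Y / rowSums(Y)
  loss_fn <- function(net, X) {
    out <- ns$nn_forward(net, X, training = TRUE, update_stats = FALSE)$out
    kld_source_loss(Y, ns$softmax_rows(out), eps = 0)
  }
  ff <- ns$nn_forward(net, X, training = TRUE, update_stats = FALSE)
  P <- ns$softmax_rows(ff$out)
  bb <- ns$nn_backward(net, ff$caches, (P - Y) / nrow(X))
  h <- 1e-6
  for (i in seq_along(net)) {
    for (p in ns$nn_param_names(net[[i]])) {
      for (idx in seq_along(net[[i]][[p]])) {
        up <- net; up[[i]][[p]][idx] <- up[[i]][[p]][idx] + h
        dn <- net; dn[[i]][[p]][idx] <- dn[[i]][[p]][idx] - h
        fd <- (loss_fn(up, X) - loss_fn(dn, X)) / (2 * h)
        expect_lt(abs(fd - bb$grads[[i]][[p]][idx]), 1e-6)
      }
    }
  }
  # input gradients (the adversarial path backpropagates through a frozen
  # domain classifier into the embedder, so dX must be exact too)
  for (idx in seq_along(X)) {
    up <- X; up[idx] <- up[idx] + h
    dn <- X; dn[idx] <- dn[idx] - h
    fd <- (loss_fn(net, up) - loss_fn(net, dn)) / (2 * h)
    expect_lt(abs(fd - bb$dX[idx]), 1e-6)
  }
})

test_that("initialisation is reproducible and heads have the right shapes", {
  m1 <- init_model(30, 5, alpha = 0.6, seed = 7)
  m2 <- init_model(30, 5, alpha = 0.6, seed = 7)
  expect_identical(param_hash(m1, "f"), param_hash(m2, "f"))
  expect_identical(param_hash(m1, "S"), param_hash(m2, "S"))
  expect_identical(param_hash(m1, "D"), param_hash(m2, "D"))
  m3 <- init_model(30, 5, alpha = 0.6, seed = 8)
  expect_false(identical(param_hash(m1, "f"), param_hash(m3, "f")))

  X <- matrix(runif(6 * 30), 6, 30)
  P <- ns$model_predict_matrix(m1, X)
  expect_equal(dim(P), c(6L, 5L))
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
  expect_true(all(P >= 0))
  expect_error(init_model(10, 1), "at least 2")
})

test_that("the embedder is shared between the two classifier paths", {
  m <- init_model(20, 3, seed = 1)
  X <- matrix(runif(5 * 20), 5, 20)
  z1 <- ns$nn_forward(m$f, X, training = FALSE)$out   # towards S
  z2 <- ns$nn_forward(m$f, X, training = FALSE)$out   # towards D
  expect_identical(z1, z2)
  d <- ns$sigmoid(ns$nn_forward(m$D, z2, training = FALSE)$out)
  expect_true(all(d > 0 & d < 1))
})

test_that("inference-mode predictions are invariant to batch composition", {
  ref <- tiny_reference(seed = 3)
  ln <- as_lognorm(ref$counts)
  ps <- minmax_scale(generate_pseudospots(ln, ref$annotation, 4, 400,
                                          seed = 1))
  model <- train_nn_wo_da(ps, training_config(pretrain_epochs = 3,
                                              batch_size = 128, seed = 2))
  scaled <- minmax_scale(ln)
  all_pred <- predict_fractions(model, scaled)
  one <- count_matrix(scaled$values[, 5, drop = FALSE], scaled$gene_ids,
                      scaled$sample_ids[5], layer = "scaled01")
  solo <- predict_fractions(model, one)
  expect_lt(max(abs(solo$fractions - all_pred$fractions[5, , drop = FALSE])),
            1e-5)
  # duplicated input spot gives identical rows
  two <- count_matrix(scaled$values[, c(5, 5)],
                      scaled$gene_ids, c("a", "b"), layer = "scaled01")
  pp <- predict_fractions(model, two)
  expect_equal(pp$fractions[1, ], pp$fractions[2, ],
               ignore_attr = TRUE)
})

test_that("checkpoints restore a model that predicts identically", {
  ref <- tiny_reference(seed = 4)
  ln <- as_lognorm(ref$counts)
  ps <- minmax_scale(generate_pseudospots(ln, ref$annotation, 3, 200,
                                          seed = 2))
  model <- train_nn_wo_da(ps, training_config(pretrain_epochs = 2,
                                              batch_size = 64, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  scaled <- minmax_scale(ln)
  expect_lt(max(abs(predict_fractions(back, scaled)$fractions -
                      predict_fractions(model, scaled)$fractions)), 1e-6)
})
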