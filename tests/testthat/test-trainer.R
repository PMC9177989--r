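make_training_fixture <- function(seed = 1, n = 800) {
  ref <- tiny_reference(seed = seed)
  ln <- as_lognorm(ref$counts)
  ps <- minmax_scale(generate_pseudospots(ln, ref$annotation, k = 4, n = n,
                                          seed = seed + 100))
  spots <- minmax_scale(ln)  # reference cells standing in as target spots
  list(ref = ref, ln = ln, ps = ps, spots = spots)
}

test_that("pretraining lowers the KLD on held-out pseudospots", {
  fx <- make_training_fixture(seed = 1)
  ref <- fx$ref
  ln <- fx$ln
  held <- minmax_scale(generate_pseudospots(ln, ref$annotation, k = 4,
                                            n = 300, seed = 999))
  model0 <- init_model(ncol(fx$ps$X), ncol(fx$ps$Y), seed = 5)
  ns <- asNamespace("spotdecon")
  kld_before <- kld_source_loss(held$Y,
                                ns$model_predict_matrix(model0, held$X))
  model <- pretrain_source(model0, fx$ps,
                           training_config(pretrain_epochs = 8,
                                           batch_size = 128, seed = 6))
  kld_after <- kld_source_loss(held$Y,
                               ns$model_predict_matrix(model, held$X))
  expect_lt(kld_after, kld_before)
  # the domain classifier is untouched by pretraining
  expect_identical(param_hash(model, "D"), param_hash(model0, "D"))
  # loss trajectory is logged and finite
  expect_length(model$history$pretrain_loss, 8)
  expect_true(all(is.finite(model$history$pretrain_loss)))
})

test_that("zero pretraining epochs is a no-op and seeds give identical models", {
  fx <- make_training_fixture(seed = 2, n = 300)
  model0 <- init_model(ncol(fx$ps$X), ncol(fx$ps$Y), seed = 1)
  same <- pretrain_source(model0, fx$ps,
                          training_config(pretrain_epochs = 0, seed = 1))
  expect_identical(param_hash(same, "f"), param_hash(model0, "f"))

  cfg <- training_config(pretrain_epochs = 3, batch_size = 64, seed = 42)
  a <- pretrain_source(model0, fx$ps, cfg)
  b <- pretrain_source(model0, fx$ps, cfg)
  expect_identical(param_hash(a, "f"), param_hash(b, "f"))
  expect_identical(param_hash(a, "S"), param_hash(b, "S"))
})

test_that("adversarial phases respect the freeze contracts", {
  fx <- make_training_fixture(seed = 3, n = 400)
  cfg <- training_config(iterations = 50, batch_size = 64,
                         pretrain_epochs = 2, seed = 7)
  model <- init_model(ncol(fx$ps$X), ncol(fx$ps$Y), seed = 8)
  model <- pretrain_source(model, fx$ps, cfg)
  h_f0 <- param_hash(model, "f")
  h_d0 <- param_hash(model, "D")
  # check_freeze asserts, at every one of the 50 iterations, that D's hash
  # is unchanged by phase A and f/S hashes unchanged by phase B
  trained <- adversarial_train(model, fx$ps, fx$spots, cfg,
                               check_freeze = TRUE)
  # both parts did train across the run as a whole
  expect_false(identical(param_hash(trained, "f"), h_f0))
  expect_false(identical(param_hash(trained, "D"), h_d0))
  expect_length(trained$history$L_s, 50)
  expect_length(trained$history$L_adv1, 50)
  expect_length(trained$history$L_adv2, 50)
})

test_that("adversarial training is reproducible and validates its inputs", {
  fx <- make_training_fixture(seed = 4, n = 300)
  cfg <- training_config(iterations = 10, batch_size = 64,
                         pretrain_epochs = 1, seed = 11)
  model <- train_nn_wo_da(fx$ps, cfg)
  a <- adversarial_train(model, fx$ps, fx$spots, cfg)
  b <- adversarial_train(model, fx$ps, fx$spots, cfg)
  expect_identical(param_hash(a, "f"), param_hash(b, "f"))
  expect_identical(param_hash(a, "D"), param_hash(b, "D"))

  wrong <- fx$spots
  wrong$gene_ids <- rev(wrong$gene_ids)
  expect_error(adversarial_train(model, fx$ps, wrong, cfg), "gene panel")
  raw_spots <- tiny_reference(seed = 4)$counts
  expect_error(adversarial_train(model, fx$ps, raw_spots, cfg), "scaled01")
})

test_that("predictions are probability rows and recover one-hot mixtures", {
  fx <- make_training_fixture(seed = 5)
  cfg <- training_config(pretrain_epochs = 10, batch_size = 128, seed = 12)
  model <- train_nn_wo_da(fx$ps, cfg)
  # single-cell 'spots' of a well-separated reference: the true type must
  # get the largest predicted fraction for most cells
  pred <- predict_fractions(model, fx$spots)
  expect_equal(unname(rowSums(pred$fractions)),
               rep(1, ncol(fx$spots$values)),
               tolerance = 1e-6)
  labels <- annotation_labels(fx$ref$annotation, fx$spots$sample_ids)
  top <- pred$cell_types[max.col(pred$fractions)]
  expect_gt(mean(top == labels), 0.8)
  # the baseline's domain classifier stays at initialisation
  fresh <- init_model(ncol(fx$ps$X), ncol(fx$ps$Y), alpha = cfg$alpha,
                      seed = cfg$seed)
  expect_identical(param_hash(model, "D"), param_hash(fresh, "D"))
})
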