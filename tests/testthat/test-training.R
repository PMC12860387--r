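test_that("k-fold splits partition the indices with near-equal sizes", {
  f10 <- kfold_split(10, 10, seed = 1)
  expect_true(all(lengths(f10) == 1))
  f25 <- kfold_split(25, 10, seed = 2)
  sizes <- sort(lengths(f25))
  expect_equal(sum(sizes == 2), 5)
  expect_equal(sum(sizes == 3), 5)
  expect_identical(sort(unlist(f25)), 1:25)
  expect_identical(kfold_split(25, 10, seed = 2), f25)
  expect_false(identical(kfold_split(25, 10, seed = 3), f25))
  expect_error(kfold_split(5, 10), "must be >=")
})

test_that("configuration objects validate their fields", {
  expect_error(train_config(epochs = -1), "epochs")
  expect_error(train_config(k_folds = 1), "k_folds")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(optimizer = "sgd"), "adam")
  expect_error(pseudospot_config(0), "n_spots")
  expect_error(pseudospot_config(5, downsample_fraction = 0), "downsample")
})

test_that("zero-epoch training returns byte-identical parameters", {
  d <- tiny_pipeline_data()
  model <- s2ae_model(40, 3, 3, d_f = 16, d_s = 8, hidden = 24, d_img = 8,
                      seed = 4)
  fit <- s2ae_fit(d$simulated, d$real,
                  train_config(epochs = 0, batch_size = 16, seed = 1),
                  loss_weights(0.1, 0.1, 0.01), model = model,
                  scales = c(60, 40, 20), out_size = 32)
  keep <- setdiff(names(model), "arch")
  expect_identical(fit$model[keep], model[keep])
  expect_equal(nrow(fit$history), 0)
})

test_that("a short joint run reduces the deconvolution loss and is reproducible", {
  d <- tiny_pipeline_data()
  cfg <- train_config(learning_rate = 1e-2, epochs = 10, batch_size = 20,
                      seed = 11)
  w <- loss_weights(0.1, 0.1, 0.01)
  fit <- s2ae_fit(d$simulated, d$real, cfg, w,
                  scales = c(60, 40, 20), out_size = 32)
  expect_lt(tail(fit$history$L_deconv, 1), fit$history$L_deconv[1])
  expect_true(all(is.finite(fit$history$L_recon)))
  # deterministic under the same seed
  fit2 <- s2ae_fit(d$simulated, d$real, cfg, w,
                   scales = c(60, 40, 20), out_size = 32)
  expect_identical(fit$model$enc, fit2$model$enc)
  expect_equal(fit$history, fit2$history)
})

test_that("configuration errors are raised before training starts", {
  d <- tiny_pipeline_data()
  no_lab <- st_dataset(d$real$expression, d$real$coords, d$real$image)
  expect_error(s2ae_fit(d$simulated, no_lab,
                        train_config(epochs = 1, batch_size = 16, seed = 1),
                        loss_weights(0.1, 0.1, 0.01)),
               "pathology labels")
  no_prop <- st_dataset(d$simulated$expression)
  expect_error(s2ae_fit(no_prop, d$real,
                        train_config(epochs = 1, batch_size = 16, seed = 1),
                        loss_weights(0, 0.1, 0)),
               "proportion labels")
})

test_that("deconvolution returns deterministic simplex rows and checks genes", {
  d <- tiny_pipeline_data()
  fit <- s2ae_fit(d$simulated, d$real,
                  train_config(epochs = 2, batch_size = 20, seed = 3),
                  loss_weights(0, 0.1, 0), use_sfe = FALSE)
  p1 <- deconvolve(fit$model, d$real)
  p2 <- deconvolve(fit$model, d$real)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(unclass(p1)) - 1) < 1e-6))
  expect_identical(rownames(p1), d$real$expression$spot_ids)

  few_genes <- st_dataset(
    spot_matrix(d$real$expression$values[, 1:10],
                d$real$expression$spot_ids,
                d$real$expression$gene_ids[1:10]),
    d$real$coords)
  expect_error(deconvolve(fit$model, few_genes), "lacks")
})

test_that("cross-validated folds cover every spot exactly once", {
  d <- tiny_pipeline_data(n_spots = 40, dim = 5)
  cv <- s2ae_cross_validate(d$simulated, d$real,
                            train_config(epochs = 1, batch_size = 20,
                                         k_folds = 3, seed = 5),
                            loss_weights(0, 0.1, 0), use_sfe = FALSE)
  got <- sort(unlist(lapply(cv$predictions, rownames)))
  expect_identical(got, sort(d$real$expression$spot_ids))
  expect_s3_class(cv$report, "metric_report")
  expect_identical(sort(unlist(cv$folds)), seq_len(25))
})

test_that("the training graph forward pass agrees with the pure-R model forward", {
  d <- tiny_pipeline_data()
  model <- s2ae_model(40, 3, 3, d_f = 16, d_s = 8, hidden = 24, d_img = 8,
                      seed = 9)
  theta <- spotmix:::flatten_params(model)
  rebuilt <- spotmix:::unflatten_params(model, theta)
  keep <- setdiff(names(model), "arch")
  expect_identical(rebuilt[keep], model[keep])

  # encoder/decoder tape forward equals the exported pure functions
  with_seed(2, X <- matrix(rnorm(6 * 40), 6, 40))
  tape <- spotmix:::ad_tape()
  nodes <- spotmix:::make_param_nodes(tape, theta)
  lat_nd <- spotmix:::ad_mlp(tape, spotmix:::ad_const(tape, X),
                             spotmix:::node_layers(nodes, "enc", 2L))
  expect_lt(max(abs(lat_nd$val - encode_latent(model, X))), 1e-12)
  dec_nd <- spotmix:::ad_decode(tape, nodes, lat_nd, model$arch)
  expect_lt(max(abs(dec_nd$val - decode_conditional(model, lat_nd$val))), 1e-12)
})
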