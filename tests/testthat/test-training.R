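test_that("reconstruction loss matches closed-form values", {
  shape <- c(4, 4, 4)
  x <- array(rep(c(0, 1), 32), dim = shape)
  expect_lte(reconstruction_loss(x, pmin(pmax(x, 1e-9), 1 - 1e-9)), 1e-6)

  half <- array(0.5, dim = shape)
  expect_equal(reconstruction_loss(half, half), log(2), tolerance = 1e-12)

  # -(0.5 log 0.25 + 0.5 log 0.75) evaluated directly
  quarter <- array(0.25, dim = shape)
  expect_equal(reconstruction_loss(half, quarter),
               -(0.5 * log(0.25) + 0.5 * log(0.75)), tolerance = 1e-12)
  expect_equal(reconstruction_loss(half, quarter), 0.8370, tolerance = 1e-4)

  expect_error(reconstruction_loss(half, array(0.5, dim = c(2, 2, 2))), "shape")
  expect_error(reconstruction_loss(half, half + 2), "outside")
})

test_that("regularization penalty is the elastic-net closed form", {
  net <- tiny_net(seed = 1)
  expect_equal(regularization_penalty(net, 0, 0), 0)

  # single weight w = 2: l1 * |2| + l2 * 4
  for (p in voxcae:::param_paths(net))
    net <- voxcae:::set_param(net, p, voxcae:::get_param(net, p) * 0)
  net$layers[[1]]$W[1] <- 2
  expect_equal(regularization_penalty(net, 1, 1), 6)
  expect_equal(regularization_penalty(net, 2, 1), 2 * 2 + 4)  # L1 term linear
  expect_error(regularization_penalty(net, -1, 0), ">= 0")
})

test_that("total objective is loss plus penalty (additivity)", {
  net <- tiny_net(seed = 3)
  l1 <- 0.01; l2 <- 0.02
  pen <- regularization_penalty(net, l1, l2)
  manual <- 0
  for (p in voxcae:::param_paths(net)) {
    if (p$f != "W") next
    w <- voxcae:::get_param(net, p)
    manual <- manual + l1 * sum(abs(w)) + l2 * sum(w^2)
  }
  expect_equal(pen, manual, tolerance = 1e-12)
})

test_that("pretraining reduces reconstruction loss and is reproducible", {
  cfg <- desk_config()
  cohort <- generate_cohort(cfg, c(AD = 3, NC = 3), seed = 21)
  ae <- build_autoencoder("cae_autoencoder", c(24, 32, 24), dropout_rate = 0,
                          seed = 4)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 4, dropout_rate = 0,
                     seed = 4)
  m1 <- pretrain_autoencoder(ae, cohort, tc)
  expect_lt(utils::tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- pretrain_autoencoder(ae, cohort, tc)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$history, m2$history)
  expect_error(pretrain_autoencoder(ae, list(), tc), "empty")
})

test_that("a zero learning rate leaves the weights untouched", {
  cfg <- desk_config()
  cohort <- generate_cohort(cfg, c(AD = 2, NC = 2), seed = 22)
  ae <- build_autoencoder("cae_autoencoder", c(24, 32, 24), dropout_rate = 0,
                          seed = 5)
  m <- pretrain_autoencoder(ae, cohort,
                            train_config(learning_rate = 0, max_epochs = 2,
                                         weight_decay = 0, dropout_rate = 0,
                                         seed = 5))
  for (p in voxcae:::param_paths(ae))
    expect_identical(voxcae:::get_param(m$net, p), voxcae:::get_param(ae, p))
  expect_equal(m$history$loss[1], utils::tail(m$history$loss, 1),
               tolerance = 1e-12)
})

test_that("fine_tune rejects degenerate tasks and reproduces exactly", {
  cfg <- desk_config()
  cohort <- generate_cohort(cfg, c(AD = 3, NC = 3), seed = 23)
  net <- build_network("cae_classifier", c(24, 32, 24), dropout_rate = 0,
                       seed = 6)
  same <- generate_cohort(cfg, c(AD = 4), seed = 24)
  expect_error(fine_tune(net, same, train_config(max_epochs = 1)), "2 classes")

  tc <- train_config(learning_rate = 1e-3, max_epochs = 3, dropout_rate = 0,
                     seed = 6)
  m1 <- fine_tune(net, cohort, tc)
  m2 <- fine_tune(net, cohort, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net, m2$net)
  expect_equal(m1$task, "AD-vs-NC")
  expect_equal(nrow(m1$history), 3)
  p <- predict_proba(m1, cohort)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("augmented training is reproducible and uses fresh draws per epoch", {
  cfg <- desk_config()
  cohort <- generate_cohort(cfg, c(AD = 2, NC = 2), seed = 25)
  net <- build_network("cae_classifier", c(24, 32, 24), dropout_rate = 0,
                       seed = 8)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 2, dropout_rate = 0,
                     augment = TRUE, seed = 9)
  m1 <- fine_tune(net, cohort, tc)
  m2 <- fine_tune(net, cohort, tc)
  expect_identical(m1$history, m2$history)
})

test_that("transfer copies the conv stack bitwise and reinitializes the head", {
  cfg <- desk_config()
  cohort <- generate_cohort(cfg, c(AD = 3, NC = 3), seed = 26)
  net <- build_network("cae_classifier", c(24, 32, 24), dropout_rate = 0,
                       seed = 10)
  src <- fine_tune(net, cohort, train_config(learning_rate = 1e-3,
                                             max_epochs = 2, dropout_rate = 0,
                                             seed = 10))
  tgt <- transfer_weights(src, target_task = "pMCI-vs-sMCI", seed = 11)
  for (nm in c("conv1", "conv2", "conv3"))
    expect_identical(get_layer(tgt, nm)$W, get_layer(src$net, nm)$W)
  expect_false(identical(get_layer(tgt, "fc1")$W, get_layer(src$net, "fc1")$W))
  expect_error(transfer_weights(src, target_task = src$task), "differ")

  # conv-stack forward pass equals the source's exactly
  v <- tiny_volume(c(24, 32, 24), seed = 12)
  expect_identical(extract_feature_maps(tgt, v, "conv3"),
                   extract_feature_maps(src$net, v, "conv3"))
})
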