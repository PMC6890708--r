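test_that("shape algebra: each pooling stage halves every spatial axis", {
  ae <- build_autoencoder("cae_autoencoder", c(24, 32, 24), seed = 1)
  v <- tiny_volume(c(24, 32, 24), seed = 1)
  h <- encode(ae, v)
  expect_equal(dim(h), c(10L, 3L, 4L, 3L))
  rec <- reconstruct(ae, v)
  expect_equal(dim(rec), c(24L, 32L, 24L))
  expect_true(all(rec > 0 & rec < 1))  # sigmoid head

  fm1 <- extract_feature_maps(build_network("cae_classifier", c(24, 32, 24),
                                            seed = 1), v, "conv1")
  expect_equal(dim(fm1), c(10L, 12L, 16L, 12L))

  expect_error(build_network("cae_classifier", c(20, 32, 24)), "divisible")
})

test_that("zero weights propagate to zero activations", {
  net <- build_network("cae_classifier", c(24, 32, 24), seed = 1)
  for (p in voxcae:::param_paths(net))
    net <- voxcae:::set_param(net, p, voxcae:::get_param(net, p) * 0)
  v <- tiny_volume(c(24, 32, 24), seed = 2)
  h <- extract_feature_maps(net, v, "conv3")
  expect_true(all(h == 0))
})

test_that("classifier outputs a softmax distribution", {
  net <- build_network("icae_classifier", c(16, 16, 16), seed = 3)
  v <- tiny_volume(c(16, 16, 16), seed = 3)
  p <- voxcae:::softmax(voxcae:::net_forward(net, v)$out)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
})

test_that("fresh builds with different seeds differ; init copies encoders", {
  n1 <- build_network("cae_classifier", c(24, 32, 24), seed = 1)
  n2 <- build_network("cae_classifier", c(24, 32, 24), seed = 2)
  expect_false(identical(get_layer(n1, "fc1")$W, get_layer(n2, "fc1")$W))

  ae <- build_autoencoder("cae_autoencoder", c(24, 32, 24), seed = 5)
  clf <- build_classifier("cae_classifier", c(24, 32, 24), init = ae, seed = 9)
  for (nm in c("conv1", "conv2", "conv3"))
    expect_identical(get_layer(clf, nm)$W, get_layer(ae, nm)$W)
  # conv weights are shape-independent across grids, but map counts must agree
  expect_error(build_classifier("cae_classifier", c(24, 32, 24), init = ae,
                                n_maps = 8L, seed = 1), "mismatch")
})

test_that("parameter counts match the closed forms", {
  # single 3x3x3 conv, 1 -> 10 maps: 27 * 10 + 10
  layers <- list(voxcae:::init_conv_layer("conv1", "conv1", 1L, 10L, 3L))
  net <- voxcae:::new_network(layers, c(8, 8, 8))
  expect_identical(count_parameters(net), 280)

  # hand-computed totals for the default architectures at desk scale
  cae <- build_network("cae_classifier", c(24, 32, 24), seed = 1)
  conv <- 280 + 2710 + 2710
  dense <- (10 * 3 * 4 * 3) * 32 + 32 + 32 * 16 + 16 + 16 * 2 + 2
  expect_identical(count_parameters(cae), conv + dense)

  icae <- build_network("icae_classifier", c(24, 32, 24), seed = 1)
  incep <- 110 + (110 + 2710) + (110 + 2710 + 2710) + 110
  out <- (40 * 3 * 4 * 3) * 2 + 2
  expect_identical(count_parameters(icae), 280 + 2710 + incep + out)
})

test_that("inception concatenates branch outputs in a fixed order", {
  inc <- withr::with_seed(8, voxcae:::init_inception_layer("inception", "i", 10L, 10L))
  x <- withr::with_seed(9, array(runif(10 * 8 * 8 * 8), c(10, 8, 8, 8)))
  out <- inception_forward(x, inc)
  expect_equal(dim(out), c(40L, 8L, 8L, 8L))

  # zeroing branch c's final conv zeroes exactly channels 21..30
  inc0 <- inc
  inc0$branches$c[[3]]$W <- inc0$branches$c[[3]]$W * 0
  inc0$branches$c[[3]]$b <- inc0$branches$c[[3]]$b * 0
  out0 <- inception_forward(x, inc0)
  expect_true(all(out0[21:30, , , ] == 0))
  expect_equal(out0[c(1:20, 31:40), , , ], out[c(1:20, 31:40), , , ])

  # all-zero weights give an all-zero module output
  incz <- inc
  for (bn in names(incz$branches))
    for (s in seq_along(incz$branches[[bn]]))
      if (incz$branches[[bn]][[s]]$type == "conv") {
        incz$branches[[bn]][[s]]$W <- incz$branches[[bn]][[s]]$W * 0
        incz$branches[[bn]][[s]]$b <- incz$branches[[bn]][[s]]$b * 0
      }
  expect_true(all(inception_forward(x, incz) == 0))

  # equals independently computed branches stacked on the channel axis
  branch_manual <- function(sub) {
    h <- x
    for (s in sub) {
      if (s$type == "conv") h <- pmax(voxcae:::conv3d_fwd(h, s$W, s$b), 0)
      else h <- voxcae:::maxpool3s1_fwd(h)$out
    }
    h
  }
  manual <- array(0, dim = c(40, 8, 8, 8))
  at <- 0
  for (bn in c("a", "b", "c", "d")) {
    hb <- branch_manual(inc$branches[[bn]])
    manual[at + seq_len(dim(hb)[1]), , , ] <- hb
    at <- at + dim(hb)[1]
  }
  expect_equal(out, manual, tolerance = 1e-12)
})

test_that("backpropagated gradients match central finite differences", {
  net <- tiny_net(c(4, 4, 4), maps = 2L, seed = 42)
  v <- withr::with_seed(1, array(runif(64), c(4, 4, 4)))
  f_logit <- function(vv) voxcae:::net_forward(net, vv)$out[1]
  fw <- voxcae:::net_forward(net, v)
  bw <- voxcae:::net_backward(net, fw$cache, c(1, 0))

  num <- numeric_gradient(f_logit, v)
  ana <- array(bw$gx, dim = dim(v))
  expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-3)

  W <- net$layers[[1]]$W
  numW <- numeric_gradient(function(w) {
    net$layers[[1]]$W <- array(w, dim = dim(W))
    voxcae:::net_forward(net, v)$out[1]
  }, W)
  expect_lt(max(abs(bw$grads[[1]]$W - numW)) / max(abs(numW)), 1e-3)

  # inception gradients on a small tensor
  inc <- withr::with_seed(4, voxcae:::init_inception_layer("inception", "i", 2L, 2L))
  x <- withr::with_seed(5, array(runif(2 * 4 * 4 * 4), c(2, 4, 4, 4)))
  gout <- withr::with_seed(6, array(rnorm(8 * 4 * 4 * 4), c(8, 4, 4, 4)))
  r <- voxcae:::incep_fwd(inc, x)
  bwi <- voxcae:::incep_bwd(inc, r$caches, r$nb, gout)
  numx <- numeric_gradient(function(xx)
    sum(voxcae:::incep_fwd(inc, array(xx, dim = dim(x)))$out * gout), x)
  expect_lt(max(abs(bwi$gx - numx)) / max(abs(numx)), 1e-3)
})

test_that("dropout only acts in training mode; inference is deterministic", {
  net <- build_network("cae_classifier", c(16, 16, 16), dropout_rate = 0.5,
                       seed = 2)
  v <- tiny_volume(c(16, 16, 16), seed = 2)
  o1 <- voxcae:::net_forward(net, v)$out
  o2 <- voxcae:::net_forward(net, v)$out
  expect_identical(o1, o2)
  fm1 <- extract_feature_maps(net, v, "conv2")
  expect_true(all(fm1 >= 0))  # post-ReLU
  t1 <- withr::with_seed(1, voxcae:::net_forward(net, v, training = TRUE)$out)
  t2 <- withr::with_seed(2, voxcae:::net_forward(net, v, training = TRUE)$out)
  expect_false(identical(t1, t2))
  expect_error(extract_feature_maps(net, v, "nope"), "unknown layer")
})
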