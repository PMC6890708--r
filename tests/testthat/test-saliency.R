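test_that("saliency of an affine scorer is exactly the weight magnitude", {
  shape <- c(6, 6, 6)
  net <- build_network("linear_classifier", shape, seed = 13)
  model <- as_model(net)
  v <- tiny_volume(shape, seed = 13)
  for (ci in 1:2) {
    m <- instance_saliency(model, v, model$labels[ci])
    expect_equal(as.numeric(m$grid),
                 abs(get_layer(net, "out")$W[, ci]), tolerance = 1e-14)
  }
  # constant scorer: zero weights, any bias -> all-zero map
  net0 <- net
  net0$layers[[2]]$W <- net0$layers[[2]]$W * 0
  net0$layers[[2]]$b <- c(3, -1)
  m0 <- instance_saliency(as_model(net0), v, "AD")
  expect_true(all(m0$grid == 0))
  expect_error(instance_saliency(model, v, "pMCI"), "unknown class")
})

test_that("saliency matches finite differences on a small random network", {
  net <- tiny_net(c(6, 6, 6), maps = 2L, seed = 31)
  model <- as_model(net)
  v <- withr::with_seed(32, array(runif(216), c(6, 6, 6)))
  m <- instance_saliency(model, v, "AD")
  num <- abs(numeric_gradient(function(x)
    voxcae:::net_forward(net, x)$out[1], v))
  expect_lt(max(abs(m$grid - num)) / max(num), 1e-3)
  expect_true(all(m$grid >= 0))
})

test_that("box smoothing has the exact impulse response and conserves mass", {
  g <- array(0, dim = c(21, 21, 21))
  g[11, 11, 11] <- 1
  s <- smooth_map(g, size = 9)
  inside <- s[3:19, 3:19, 3:19]
  expect_equal(sum(s), 1, tolerance = 1e-12)          # mass conserved
  expect_equal(max(s), 1 / 729, tolerance = 1e-15)    # flat top
  win <- s[7:15, 7:15, 7:15]
  expect_true(all(abs(win - 1 / 729) < 1e-15))
  s0 <- s
  s0[7:15, 7:15, 7:15] <- 0
  expect_true(all(s0 == 0))                            # zero outside the window

  const <- smooth_map(array(2.5, dim = c(8, 8, 8)), size = 3)
  expect_true(all(abs(const - 2.5) < 1e-12))           # reflection keeps constants
  expect_error(smooth_map(g, size = 4), "odd")
})

test_that("group saliency normalizes to [0, 1] and ignores duplication", {
  net <- tiny_net(c(6, 6, 6), maps = 2L, seed = 33)
  model <- as_model(net)
  cfgv <- function(seed) {
    v <- withr::with_seed(seed, array(runif(216), c(6, 6, 6)))
    vox_scan(vox_volume(v), "AD", paste0("s", seed))
  }
  scans <- lapply(34:36, cfgv)
  g1 <- group_saliency(model, scans, "AD", smooth_size = 3)
  expect_gte(min(g1$grid), 0)
  expect_equal(max(g1$grid), 1)
  g2 <- group_saliency(model, c(scans, scans), "AD", smooth_size = 3)
  expect_equal(g1$grid, g2$grid, tolerance = 1e-12)

  # single scan: its smoothed instance map, min-max normalized
  gs <- group_saliency(model, scans[1], "AD", smooth_size = 3)
  ref <- smooth_map(instance_saliency(model, scans[[1]]$volume, "AD"), 3)$grid
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(gs$grid, ref, tolerance = 1e-12)

  expect_error(group_saliency(model, list(), "AD"), "no scans")
  mixed <- c(scans[1], list(vox_scan(scans[[2]]$volume, "NC", "x")))
  expect_error(group_saliency(model, mixed, "AD"), "target class")
})

test_that("supervoxel segmentation partitions the grid", {
  v <- tiny_volume(c(12, 12, 12), seed = 40)
  seg <- supervoxel_segment(v, n_segments = 20)
  expect_equal(dim(seg), dim(v$data))
  expect_equal(sort(unique(as.integer(seg))), seq_len(max(seg)))
  expect_gte(max(seg), 1)

  one <- supervoxel_segment(v, n_segments = 1)
  expect_true(all(one == 1))
  expect_error(supervoxel_segment(v, n_segments = 1e6), "exceeds")
})

test_that("supervoxels recover a separable two-block volume exactly", {
  g <- array(0, dim = c(8, 8, 8))
  g[5:8, , ] <- 1
  seg <- supervoxel_segment(vox_volume(g), n_segments = 2, compactness = 0.1)
  expect_equal(max(seg), 2L)
  expect_length(unique(as.integer(seg[1:4, , ])), 1)
  expect_length(unique(as.integer(seg[5:8, , ])), 1)
  expect_false(seg[1, 1, 1] == seg[8, 8, 8])
})

test_that("supervoxel count stays near the request on phantom data", {
  s <- generate_scan(desk_config(), "NC", seed = 44)
  for (n in c(40, 100)) {
    seg <- supervoxel_segment(s$volume, n_segments = n)
    expect_gte(max(seg), 0.8 * n)
    expect_lte(max(seg), 1.35 * n)
  }
})

test_that("occluding the lesion-covering supervoxel flips the oracle", {
  cfg <- desk_config()
  mask <- phantom_lesion_mask(cfg, "AD")
  head <- voxcae:::ellipsoid_mask(cfg$grid_shape, cfg$head_center,
                                  cfg$head_radii)
  oracle <- calibrate_oracle(cfg, c("AD", "NC"), n = 20, seed = 3)
  scans <- generate_cohort(cfg, c(NC = 6), seed = 50)
  scans <- Filter(function(s) predict_label(oracle, s$volume) == "NC", scans)

  # anatomy-aligned segmentation: lesion region / rest of head / background
  seg <- array(3L, dim = cfg$grid_shape)
  seg[head] <- 2L
  seg[mask] <- 1L
  imp <- occlusion_simulation(oracle, scans, seg, from = "NC", to = "AD")
  expect_equal(imp$n_scans, length(scans))
  # zeroing the whole lesion region sends the mask mean to 0 < threshold
  expect_equal(imp$counts[1], imp$n_scans)
  # the background supervoxel is already zero: occlusion changes nothing
  expect_equal(imp$counts[3], 0L)
  expect_true(all(imp$counts <= imp$n_scans))
  # derived voxel grid carries its supervoxel's count
  expect_true(all(imp$grid[seg == 1L] == imp$counts[1]))

  # with a fine SLIC segmentation no single supervoxel covers enough of the
  # lesion to flip this oracle, and supervoxels outside the mask never flip
  slic <- supervoxel_segment(scans[[1]]$volume, n_segments = 60)
  imp2 <- occlusion_simulation(oracle, scans, slic, from = "NC", to = "AD")
  overlap <- vapply(seq_len(max(slic)),
                    function(k) sum(mask[slic == k]) > 0, TRUE)
  expect_true(all(imp2$counts[!overlap] == 0))
  expect_true(all(imp2$counts <= imp2$n_scans))
  expect_error(occlusion_simulation(oracle, scans, slic[1:10, , ],
                                    from = "NC", to = "AD"), "shape")
})

test_that("threshold_roi selects voxels at the stated fraction of max", {
  g <- array(seq(0, 1, length.out = 27), dim = c(3, 3, 3))
  roi <- threshold_roi(g, 0.8)
  expect_identical(roi, g >= 0.8)
  expect_true(all(threshold_roi(array(2, dim = c(2, 2, 2)), 0.8)))
  expect_false(any(threshold_roi(array(0, dim = c(2, 2, 2)), 0.8)))
  expect_error(threshold_roi(g, 0), "fraction")
  expect_error(threshold_roi(g, 1.2), "fraction")
})
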