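# Shared fixtures: tiny volumes, a small phantom configuration, and a
# miniature network for gradient checks. Everything is generated in code.

tiny_volume <- function(shape = c(6, 6, 6), seed = 1) {
  withr::with_seed(seed, vox_volume(array(runif(prod(shape)), dim = shape)))
}

desk_config <- function(...) phantom_config(...)

# conv block + flatten + dense head on a small grid; exercises every
# gradient path except the inception module
tiny_net <- function(shape = c(4, 4, 4), maps = 2L, seed = 42) {
  withr::with_seed(seed, {
    layers <- c(voxcae:::conv_block("conv1", 1L, maps, 0),
                list(list(type = "flatten", block = "flatten")),
                list(voxcae:::init_dense_layer("out", "out",
                                               maps * prod(shape %/% 2L), 2L)))
    voxcae:::new_network(layers, shape, "custom")
  })
}

# wrap a network as a two-class model without training (for saliency tests)
as_model <- function(net, labels = c("AD", "NC")) {
  structure(list(net = net, history = data.frame(),
                 task = paste(labels, collapse = "-vs-"), labels = labels,
                 config = NULL),
            class = "vox_model")
}

# central finite-difference gradient of f at x (slow; use on tiny inputs)
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independently coded trilinear interpolation oracle (align-corners)
trilinear_oracle <- function(v, target) {
  src <- dim(v)
  out <- array(0, dim = target)
  for (k in seq_len(target[3])) for (j in seq_len(target[2]))
    for (i in seq_len(target[1])) {
      p <- c(i, j, k) - 1
      s <- ifelse(target > 1, p * (src - 1) / (target - 1), 0)
      lo <- pmin(floor(s), src - 1)
      hi <- pmin(lo + 1, src - 1)
      f <- s - lo
      acc <- 0
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
          (if (cc) f[3] else 1 - f[3])
        idx <- ifelse(c(a, b, cc) == 1, hi, lo) + 1
        acc <- acc + w * v[idx[1], idx[2], idx[3]]
      }
      out[i, j, k] <- acc
    }
  out
}
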