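# Volumetric network architectures: plain convolutional (CAE-style) and
# inception-module (ICAE-style) encoders, their mirrored autoencoders, and
# the derived classifiers. Networks are plain R lists of primitive layers;
# all tensor work happens in the compiled kernels. Feature tensors carry
# dim (channels, x, y, z).

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_apply <- function(x, fun) {
  switch(fun,
         relu = relu_fwd(x),
         selu = ifelse(x > 0, SELU_LAMBDA * x,
                       SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1)),
         sigmoid = stats::plogis(x),
         linear = x,
         stop("unknown activation: ", fun))
}

act_deriv <- function(x, fun) {
  switch(fun,
         relu = (x > 0) + 0,
         selu = ifelse(x > 0, SELU_LAMBDA, SELU_LAMBDA * SELU_ALPHA * exp(x)),
         sigmoid = {
           s <- stats::plogis(x)
           s * (1 - s)
         },
         linear = array(1, dim = if (is.null(dim(x))) length(x) else dim(x)),
         stop("unknown activation: ", fun))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# variance-scaling (fan-in) initialization
init_conv_layer <- function(name, block, cin, cout, k = 3L) {
  W <- array(rnorm(cin * k^3 * cout, sd = sqrt(1 / (cin * k^3))),
             dim = c(cin, k, k, k, cout))
  list(type = "conv", name = name, block = block, W = W, b = numeric(cout))
}

init_dense_layer <- function(name, block, nin, nout) {
  list(type = "dense", name = name, block = block,
       W = matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout),
       b = numeric(nout))
}

# the four parallel branches of the 3D inception module; each branch emits
# maps_per_branch channels and the outputs are concatenated (a, b, c, d)
# along the channel axis. The 5x5x5 path is factorized into two 3x3x3
# convolutions; the 1x1x1 bottlenecks keep the input width.
init_inception_layer <- function(name, block, cin, maps_per_branch = 10L) {
  m <- maps_per_branch
  list(type = "inception", name = name, block = block,
       branches = list(
         a = list(init_conv_layer("a1", block, cin, m, 1L)),
         b = list(init_conv_layer("b1", block, cin, cin, 1L),
                  init_conv_layer("b2", block, cin, m, 3L)),
         c = list(init_conv_layer("c1", block, cin, cin, 1L),
                  init_conv_layer("c2", block, cin, cin, 3L),
                  init_conv_layer("c3", block, cin, m, 3L)),
         d = list(list(type = "pool_s1"),
                  init_conv_layer("d1", block, cin, m, 1L))))
}

new_network <- function(layers, input_shape, variant = "custom",
                        n_maps = NA_integer_) {
  structure(list(variant = variant, input_shape = as.integer(input_shape),
                 n_maps = n_maps, layers = layers),
            class = "vox_network")
}

# Block layout: convolution, Gaussian dropout on the pre-activation maps,
# rectifier, then the 2x2x2 pooling (encoder) or upsampling (decoder) stage.
conv_block <- function(name, cin, cout, dropout_rate) {
  list(init_conv_layer(name, name, cin, cout, 3L),
       list(type = "gdropout", block = name, rate = dropout_rate),
       list(type = "act", block = name, fun = "relu"),
       list(type = "pool", block = name))
}

decoder_block <- function(name, cin, cout, dropout_rate) {
  list(init_conv_layer(name, name, cin, cout, 3L),
       list(type = "gdropout", block = name, rate = dropout_rate),
       list(type = "act", block = name, fun = "relu"),
       list(type = "upsample", block = name))
}

#' Build a volumetric network
#'
#' Constructs one of the package's architectures with freshly initialized
#' weights (variance-scaling, fan-in):
#'
#' * `"cae_classifier"`: three 3x3x3 convolution blocks with `n_maps`
#'   feature maps each (conv, Gaussian dropout, ReLU, 2x2x2 max-pool),
#'   then fully connected layers of 32 and 16 SELU units and a 2-unit
#'   softmax output.
#' * `"icae_classifier"`: two convolution blocks, one inception module
#'   emitting `4 * n_maps` maps, a final pooling stage, and the 2-unit
#'   output directly on the flattened maps (no hidden dense layers).
#' * `"cae_autoencoder"` / `"icae_autoencoder"`: the matching encoder with
#'   a mirrored decoder (conv, dropout, ReLU, 2x nearest-neighbour
#'   upsampling per stage) and a sigmoid reconstruction head, so the
#'   reconstruction lies in (0, 1). Encoder and decoder weights are untied.
#' * `"linear_classifier"`: flatten plus a 2-unit affine output; the
#'   motivating case for which the saliency map is exactly the weight
#'   magnitude.
#'
#' Spatial dimensions must be divisible by 8 (three pooling stages) for all
#' but the linear variant.
#'
#' @param variant Architecture name, see above.
#' @param input_shape Integer length-3 input grid.
#' @param n_maps Feature maps per convolution block.
#' @param dropout_rate Gaussian dropout drop-rate `p`; activations are
#'   multiplied during training by `N(1, p / (1 - p))` noise. `0` disables.
#' @param fc_sizes Hidden dense widths of the CAE classifier.
#' @param seed Integer seed for the initialization draws; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `vox_network`.
#' @export
build_network <- function(variant = c("cae_classifier", "icae_classifier",
                                      "cae_autoencoder", "icae_autoencoder",
                                      "linear_classifier"),
                          input_shape = c(24, 32, 24), n_maps = 10L,
                          dropout_rate = 0.5, fc_sizes = c(32L, 16L),
                          seed = NULL) {
  variant <- match.arg(variant)
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape > 0))
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (variant != "linear_classifier" && any(input_shape %% 8L != 0L))
    stop("input dimensions must be divisible by 8 (three 2x2x2 pooling stages)")
  build <- function() {
    m <- as.integer(n_maps)
    pooled <- input_shape %/% 8L
    layers <- switch(
      variant,
      cae_classifier = c(
        conv_block("conv1", 1L, m, dropout_rate),
        conv_block("conv2", m, m, dropout_rate),
        conv_block("conv3", m, m, dropout_rate),
        list(list(type = "flatten", block = "flatten")),
        list(init_dense_layer("fc1", "fc1", m * prod(pooled), fc_sizes[1]),
             list(type = "act", block = "fc1", fun = "selu"),
             init_dense_layer("fc2", "fc2", fc_sizes[1], fc_sizes[2]),
             list(type = "act", block = "fc2", fun = "selu"),
             init_dense_layer("out", "out", fc_sizes[2], 2L))),
      icae_classifier = c(
        conv_block("conv1", 1L, m, dropout_rate),
        conv_block("conv2", m, m, dropout_rate),  # dropout precedes inception
        list(init_inception_layer("inception", "inception", m, m),
             list(type = "pool", block = "inception"),
             list(type = "flatten", block = "flatten"),
             init_dense_layer("out", "out", 4L * m * prod(pooled), 2L))),
      cae_autoencoder = c(
        conv_block("conv1", 1L, m, dropout_rate),
        conv_block("conv2", m, m, dropout_rate),
        conv_block("conv3", m, m, dropout_rate),
        decoder_block("dec3", m, m, dropout_rate),
        decoder_block("dec2", m, m, dropout_rate),
        decoder_block("dec1", m, m, dropout_rate),
        list(init_conv_layer("recon", "recon", m, 1L, 3L),
             list(type = "act", block = "recon", fun = "sigmoid"))),
      icae_autoencoder = c(
        conv_block("conv1", 1L, m, dropout_rate),
        conv_block("conv2", m, m, dropout_rate),
        list(init_inception_layer("inception", "inception", m, m),
             list(type = "pool", block = "inception")),
        decoder_block("dec3", 4L * m, m, dropout_rate),
        decoder_block("dec2", m, m, dropout_rate),
        decoder_block("dec1", m, m, dropout_rate),
        list(init_conv_layer("recon", "recon", m, 1L, 3L),
             list(type = "act", block = "recon", fun = "sigmoid"))),
      linear_classifier = list(
        list(type = "flatten", block = "flatten"),
        init_dense_layer("out", "out", prod(input_shape), 2L)))
    new_network(layers, input_shape, variant, n_maps)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.vox_network <- function(x, ...) {
  cat(sprintf("<vox_network> %s, input %s, %s trainable parameters\n",
              x$variant, paste(x$input_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

as_input_tensor <- function(v) {
  d <- if (inherits(v, "vox_volume")) v$data else v
  if (length(dim(d)) == 3L) dim(d) <- c(1L, dim(d))
  d
}

# ---- forward -------------------------------------------------------------

incep_fwd <- function(layer, x, training = FALSE) {
  branch_fwd <- function(sub) {
    h <- x
    caches <- list()
    for (i in seq_along(sub)) {
      s <- sub[[i]]
      if (s$type == "conv") {
        caches[[i]] <- list(x = h)
        h <- conv3d_fwd(h, s$W, s$b)
        caches[[i]]$pre <- h
        h <- act_apply(h, "relu")
      } else {  # pool_s1
        r <- maxpool3s1_fwd(h)
        caches[[i]] <- list(idx = r$idx, xdim = dim(h))
        h <- r$out
      }
    }
    list(out = h, caches = caches)
  }
  res <- lapply(layer$branches, branch_fwd)
  d <- dim(res[[1]]$out)
  nb <- vapply(res, function(r) dim(r$out)[1], 0L)
  out <- array(0, dim = c(sum(nb), d[2], d[3], d[4]))
  at <- 0L
  for (r in res) {
    cb <- dim(r$out)[1]
    out[at + seq_len(cb), , , ] <- r$out
    at <- at + cb
  }
  list(out = out, caches = lapply(res, `[[`, "caches"), nb = nb)
}

#' Run the 3D inception module forward
#'
#' Applies the four branches of an inception layer to a feature tensor and
#' concatenates their outputs along the channel axis (branch order a, b, c,
#' d). Spatial dimensions are preserved.
#'
#' @param h Feature tensor, dim `(channels, x, y, z)`.
#' @param layer An inception layer, e.g. `get_layer(net, "inception")`.
#' @return Feature tensor with `4 * n_maps` channels.
#' @export
inception_forward <- function(h, layer) {
  stopifnot(identical(layer$type, "inception"))
  incep_fwd(layer, h)$out
}

net_forward <- function(net, v, training = FALSE) {
  x <- as_input_tensor(v)
  if (!identical(dim(x)[-1], net$input_shape))
    stop("input shape ", paste(dim(x)[-1], collapse = "x"),
         " does not match network input ",
         paste(net$input_shape, collapse = "x"))
  cache <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    c_i <- list()
    x <- switch(
      l$type,
      conv = {
        c_i$x <- x
        conv3d_fwd(x, l$W, l$b)
      },
      gdropout = {
        if (training && l$rate > 0) {
          noise <- array(rnorm(length(x), mean = 1,
                               sd = sqrt(l$rate / (1 - l$rate))), dim = dim(x))
          c_i$noise <- noise
          x * noise
        } else x
      },
      act = {
        c_i$pre <- x
        act_apply(x, l$fun)
      },
      pool = {
        r <- maxpool2_fwd(x)
        c_i$idx <- r$idx
        c_i$xdim <- dim(x)
        r$out
      },
      upsample = upsample2_fwd(x),
      flatten = {
        c_i$xdim <- dim(x)
        as.numeric(x)
      },
      dense = {
        c_i$x <- x
        drop(x %*% l$W) + l$b
      },
      inception = {
        r <- incep_fwd(l, x, training)
        c_i$branches <- r$caches
        c_i$nb <- r$nb
        r$out
      },
      stop("unknown layer type: ", l$type))
    cache[[i]] <- c_i
    cache[[i]]$out <- x
  }
  list(out = x, cache = cache)
}

# ---- backward ------------------------------------------------------------

incep_bwd <- function(layer, caches, nb, g) {
  gx_total <- NULL
  grads <- list()
  at <- 0L
  for (bn in names(layer$branches)) {
    sub <- layer$branches[[bn]]
    cb <- nb[[bn]]
    gb <- g[at + seq_len(cb), , , , drop = FALSE]
    dim(gb) <- c(cb, dim(g)[2:4])
    at <- at + cb
    bgrads <- vector("list", length(sub))
    for (i in rev(seq_along(sub))) {
      s <- sub[[i]]
      cc <- caches[[bn]][[i]]
      if (s$type == "conv") {
        gb <- relu_bwd(gb, cc$pre)
        r <- conv3d_bwd(cc$x, s$W, gb)
        bgrads[[i]] <- list(W = r$gw, b = r$gb)
        gb <- r$gx
      } else {
        gb <- maxpool3s1_bwd(gb, cc$idx, cc$xdim)
      }
    }
    grads[[bn]] <- bgrads
    gx_total <- if (is.null(gx_total)) gb else gx_total + gb
  }
  list(gx = gx_total, branches = grads)
}

# Backpropagate `g`, the gradient w.r.t. the output of layer `from`,
# down to the input. Returns the input gradient and per-layer weight grads.
net_backward <- function(net, cache, g, from = length(net$layers)) {
  grads <- vector("list", length(net$layers))
  for (i in seq(from, 1L)) {
    l <- net$layers[[i]]
    g <- switch(
      l$type,
      conv = {
        r <- conv3d_bwd(cache[[i]]$x, l$W, g)
        grads[[i]] <- list(W = r$gw, b = r$gb)
        r$gx
      },
      gdropout = if (is.null(cache[[i]]$noise)) g else g * cache[[i]]$noise,
      act = if (l$fun == "relu") relu_bwd(g, cache[[i]]$pre)
            else g * act_deriv(cache[[i]]$pre, l$fun),
      pool = maxpool2_bwd(g, cache[[i]]$idx, cache[[i]]$xdim),
      upsample = upsample2_bwd(g),
      flatten = {
        dim(g) <- cache[[i]]$xdim
        g
      },
      dense = {
        xv <- cache[[i]]$x
        grads[[i]] <- list(W = outer(as.numeric(xv), g), b = g)
        as.numeric(l$W %*% g)
      },
      inception = {
        r <- incep_bwd(l, cache[[i]]$branches, cache[[i]]$nb, g)
        grads[[i]] <- list(branches = r$branches)
        r$gx
      })
  }
  list(gx = g, grads = grads)
}

# ---- parameter bookkeeping ----------------------------------------------

# flat list of parameter locations: list(i, br, s, f) addressing
# net$layers[[i]] ($branches[[br]][[s]]) $W / $b
param_paths <- function(net) {
  paths <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type %in% c("conv", "dense")) {
      paths[[length(paths) + 1L]] <- list(i = i, f = "W")
      paths[[length(paths) + 1L]] <- list(i = i, f = "b")
    } else if (l$type == "inception") {
      for (bn in names(l$branches))
        for (s in seq_along(l$branches[[bn]]))
          if (l$branches[[bn]][[s]]$type == "conv")
            for (f in c("W", "b"))
              paths[[length(paths) + 1L]] <-
                list(i = i, br = bn, s = s, f = f)
    }
  }
  paths
}

get_param <- function(net, p) {
  l <- net$layers[[p$i]]
  if (is.null(p$br)) l[[p$f]] else l$branches[[p$br]][[p$s]][[p$f]]
}

set_param <- function(net, p, val) {
  if (is.null(p$br)) net$layers[[p$i]][[p$f]] <- val
  else net$layers[[p$i]]$branches[[p$br]][[p$s]][[p$f]] <- val
  net
}

get_grad <- function(grads, p) {
  g <- grads[[p$i]]
  if (is.null(p$br)) g[[p$f]] else g$branches[[p$br]][[p$s]][[p$f]]
}

#' Count trainable parameters
#'
#' Exact integer count of every weight and bias scalar in the network,
#' including all inception branches.
#'
#' @param net A `vox_network` or trained model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "vox_model")) net <- net$net
  sum(vapply(param_paths(net), function(p) length(get_param(net, p)), 0))
}

#' Retrieve a named layer
#'
#' @param net A `vox_network` or trained model.
#' @param name Layer name (e.g. `"conv1"`, `"inception"`, `"out"`).
#' @return The layer object.
#' @export
get_layer <- function(net, name) {
  if (inherits(net, "vox_model")) net <- net$net
  for (l in net$layers) if (identical(l$name, name)) return(l)
  stop("no layer named '", name, "'")
}

# names of the convolutional / inception layers shared between encoder,
# autoencoder and classifier variants
encoder_layer_names <- function(net) {
  nm <- vapply(net$layers,
               function(l) if (l$type %in% c("conv", "inception") &&
                               grepl("^(conv|inception)", l$name %||% ""))
                 l$name else NA_character_, "")
  nm[!is.na(nm)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# copy W/b of identically named conv/inception layers from one net to another
copy_encoder_weights <- function(from, to) {
  shared <- intersect(encoder_layer_names(from), encoder_layer_names(to))
  if (length(shared) == 0) stop("no shared encoder layers to copy")
  for (nm in shared) {
    i_from <- which(vapply(from$layers, function(l) identical(l$name, nm), TRUE))
    i_to <- which(vapply(to$layers, function(l) identical(l$name, nm), TRUE))
    lf <- from$layers[[i_from]]
    lt <- to$layers[[i_to]]
    if (lf$type == "conv") {
      if (!identical(dim(lf$W), dim(lt$W)))
        stop("shape mismatch for layer '", nm, "'")
      to$layers[[i_to]]$W <- lf$W
      to$layers[[i_to]]$b <- lf$b
    } else {
      for (bn in names(lf$branches))
        for (s in seq_along(lf$branches[[bn]]))
          if (lf$branches[[bn]][[s]]$type == "conv") {
            if (!identical(dim(lf$branches[[bn]][[s]]$W),
                           dim(lt$branches[[bn]][[s]]$W)))
              stop("shape mismatch for layer '", nm, "'")
            to$layers[[i_to]]$branches[[bn]][[s]]$W <- lf$branches[[bn]][[s]]$W
            to$layers[[i_to]]$branches[[bn]][[s]]$b <- lf$branches[[bn]][[s]]$b
          }
    }
  }
  to
}

#' Build a classifier, optionally initialized from a pretrained encoder
#'
#' Convolutional (and inception) layers take the pretrained encoder weights
#' when `init` is given; dense and output layers are always freshly
#' initialized.
#'
#' @param variant `"cae_classifier"` or `"icae_classifier"`.
#' @param input_shape Input grid shape.
#' @param init Optional pretrained autoencoder (`vox_network` or the result
#'   of [pretrain_autoencoder()]) whose encoder weights are copied in.
#' @param ... Passed to [build_network()].
#' @return A `vox_network` classifier.
#' @export
build_classifier <- function(variant = c("cae_classifier", "icae_classifier"),
                             input_shape = c(24, 32, 24), init = NULL, ...) {
  variant <- match.arg(variant)
  net <- build_network(variant, input_shape, ...)
  if (!is.null(init)) {
    if (inherits(init, "vox_model")) init <- init$net
    net <- copy_encoder_weights(init, net)
  }
  net
}

#' Build an autoencoder network
#'
#' @param variant `"cae_autoencoder"` or `"icae_autoencoder"`.
#' @param input_shape Input grid shape (divisible by 8).
#' @param ... Passed to [build_network()].
#' @return A `vox_network` autoencoder.
#' @export
build_autoencoder <- function(variant = c("cae_autoencoder", "icae_autoencoder"),
                              input_shape = c(24, 32, 24), ...) {
  build_network(match.arg(variant), input_shape, ...)
}

#' Encode and decode with an autoencoder
#'
#' `encode()` returns the bottleneck feature tensor; `decode()` maps a
#' bottleneck tensor back to a reconstruction in (0, 1); `reconstruct()`
#' chains the two. Dropout is inactive (inference mode).
#'
#' @param net An autoencoder `vox_network`.
#' @param v A [vox_volume()] or 3D array.
#' @return `encode`: feature tensor; `reconstruct`: 3D array in (0, 1).
#' @export
encode <- function(net, v) {
  i <- encoder_end_index(net)
  fw <- net_forward(net, v)
  fw$cache[[i]]$out
}

encoder_end_index <- function(net) {
  enc_blocks <- c("conv1", "conv2", "conv3", "inception")
  idx <- which(vapply(net$layers, function(l) l$block %in% enc_blocks, TRUE))
  max(idx)
}

#' @rdname encode
#' @param h Bottleneck feature tensor as returned by `encode()`.
#' @export
decode <- function(net, h) {
  i0 <- encoder_end_index(net) + 1L
  x <- h
  for (i in seq(i0, length(net$layers))) {
    l <- net$layers[[i]]
    x <- switch(l$type,
                conv = conv3d_fwd(x, l$W, l$b),
                gdropout = x,
                act = act_apply(x, l$fun),
                upsample = upsample2_fwd(x),
                stop("unexpected layer in decoder: ", l$type))
  }
  array(x, dim = dim(x)[-1])
}

#' @rdname encode
#' @export
reconstruct <- function(net, v) decode(net, encode(net, v))

#' Extract a post-activation feature tensor
#'
#' Runs the network in inference mode (dropout disabled) and returns the
#' output of the named block: for a convolution block this is the tensor
#' after its pooling stage, for the inception block after its pooling
#' stage, and for dense blocks the activation vector.
#'
#' @param net A `vox_network` or trained model.
#' @param v Input [vox_volume()] or array.
#' @param layer_name Block name, e.g. `"conv1"` or `"inception"`.
#' @return The feature tensor (`(channels, x, y, z)` array) or vector.
#' @export
extract_feature_maps <- function(net, v, layer_name) {
  if (inherits(net, "vox_model")) net <- net$net
  blocks <- vapply(net$layers, function(l) l$block, "")
  idx <- which(blocks == layer_name)
  if (length(idx) == 0) stop("unknown layer name: ", layer_name)
  fw <- net_forward(net, v)
  fw$cache[[max(idx)]]$out
}
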