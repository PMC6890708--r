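# Optimization: Adam with decoupled weight decay, elastic-net style
# L1/L2 penalties on the weights (biases excluded), unsupervised
# reconstruction pretraining and supervised fine-tuning, plus
# source-to-target transfer of the convolutional stack.

#' Training configuration
#'
#' Optimizer and regularization settings shared by pretraining and
#' fine-tuning. Defaults follow the reference setup for this family of
#' models: Adam with learning rate 1e-4, both moment decays 0.9 (note the
#' unusual second-moment decay; it is configurable), decoupled weight decay
#' 1e-5, mini-batches of 10 and up to 200 epochs. The L1/L2 penalty weights
#' are the grid-searched regularizers and are kept separate from the fixed
#' weight decay.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 First/second moment decay rates.
#' @param weight_decay Decoupled per-step weight decay on weight matrices.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param dropout_rate Gaussian dropout drop-rate applied to the network's
#'   dropout layers for this run (`NULL` keeps the network's own rates).
#' @param l1_weight,l2_weight Penalty factors on the summed `|w|` and `w^2`.
#' @param augment Apply on-the-fly augmentation each epoch (classifiers).
#' @param augment_params An [augment_params()] object.
#' @param seed Integer seed making the run fully reproducible.
#' @return An object of class `vox_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.9,
                         weight_decay = 1e-5, batch_size = 10L,
                         max_epochs = 200L, dropout_rate = NULL,
                         l1_weight = 0, l2_weight = 0,
                         augment = FALSE, augment_params = NULL, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (l1_weight < 0 || l2_weight < 0) stop("penalty weights must be >= 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 dropout_rate = dropout_rate,
                 l1_weight = l1_weight, l2_weight = l2_weight,
                 augment = augment,
                 augment_params = augment_params %||% default_augment_params(),
                 seed = as.integer(seed)),
            class = "vox_train_config")
}

#' Voxelwise reconstruction cross-entropy
#'
#' Mean over voxels (and scans, for lists) of
#' `-[x log x' + (1 - x) log(1 - x')]`, with the convention `0 log 0 = 0`.
#' The reconstruction is clamped to `[eps, 1 - eps]` before the logs.
#'
#' @param x Original intensities in `[0, 1]` ([vox_volume()] or array).
#' @param x_rec Reconstruction in `(0, 1)`, same shape.
#' @param eps Clamping tolerance.
#' @return Non-negative scalar, the per-voxel mean cross-entropy.
#' @export
reconstruction_loss <- function(x, x_rec, eps = 1e-7) {
  if (inherits(x, "vox_volume")) x <- x$data
  if (inherits(x_rec, "vox_volume")) x_rec <- x_rec$data
  if (!identical(dim(x), dim(x_rec))) stop("shape mismatch")
  if (min(x_rec) < -eps || max(x_rec) > 1 + eps)
    stop("reconstruction values outside (0, 1)")
  xr <- pmin(pmax(x_rec, eps), 1 - eps)
  mean(-(x * log(xr) + (1 - x) * log(1 - xr)))
}

#' Elastic-net penalty over the network weights
#'
#' `l1 * sum(|w|) + l2 * sum(w^2)` over all convolution and dense weight
#' arrays; biases are excluded.
#'
#' @param net A `vox_network` or trained model.
#' @param l1_weight,l2_weight Non-negative penalty factors.
#' @return Scalar penalty.
#' @export
regularization_penalty <- function(net, l1_weight = 0, l2_weight = 0) {
  if (inherits(net, "vox_model")) net <- net$net
  if (l1_weight < 0 || l2_weight < 0) stop("penalty weights must be >= 0")
  tot <- 0
  for (p in param_paths(net)) {
    if (p$f != "W") next
    w <- get_param(net, p)
    tot <- tot + l1_weight * sum(abs(w)) + l2_weight * sum(w * w)
  }
  tot
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(net, paths) {
  lapply(paths, function(p) {
    w <- get_param(net, p)
    zero <- if (is.null(dim(w))) numeric(length(w)) else array(0, dim = dim(w))
    list(m = zero, v = zero)
  })
}

# one optimizer step; returns list(net, state). Penalty gradients and
# decoupled weight decay act on weight arrays only.
adam_step <- function(net, grads, state, paths, cfg, t) {
  lr <- cfg$learning_rate
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    g <- get_grad(grads, p)
    w <- get_param(net, p)
    if (p$f == "W") {
      if (cfg$l1_weight > 0) g <- g + cfg$l1_weight * sign(w)
      if (cfg$l2_weight > 0) g <- g + 2 * cfg$l2_weight * w
    }
    st <- state[[k]]
    st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
    st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g * g
    mhat <- st$m / (1 - cfg$beta1^t)
    vhat <- st$v / (1 - cfg$beta2^t)
    w <- w - lr * mhat / (sqrt(vhat) + 1e-8)
    if (p$f == "W" && cfg$weight_decay > 0) w <- w - lr * cfg$weight_decay * w
    net <- set_param(net, p, w)
    state[[k]] <- st
  }
  list(net = net, state = state)
}

# accumulate two per-layer gradient structures
grads_add <- function(a, b, paths) {
  if (is.null(a)) return(b)
  for (p in paths) {
    g <- get_grad(a, p) + get_grad(b, p)
    if (is.null(p$br)) a[[p$i]][[p$f]] <- g
    else a[[p$i]]$branches[[p$br]][[p$s]][[p$f]] <- g
  }
  a
}

grads_scale <- function(a, s, paths) {
  for (p in paths) {
    g <- get_grad(a, p) * s
    if (is.null(p$br)) a[[p$i]][[p$f]] <- g
    else a[[p$i]]$branches[[p$br]][[p$s]][[p$f]] <- g
  }
  a
}

apply_dropout_rate <- function(net, rate) {
  if (is.null(rate)) return(net)
  for (i in seq_along(net$layers))
    if (net$layers[[i]]$type == "gdropout") net$layers[[i]]$rate <- rate
  net
}

# ---- unsupervised pretraining -------------------------------------------

#' Pretrain an autoencoder on unlabeled volumes
#'
#' Minimizes the voxelwise reconstruction cross-entropy (plus the
#' configured penalties) with Adam over mini-batches; labels of the scans
#' are ignored. The backward pass starts at the pre-sigmoid reconstruction
#' logits, where the cross-entropy gradient is simply
#' `(x_rec - x) / n_voxels`. Fully reproducible from `cfg$seed`.
#'
#' @param net An autoencoder `vox_network`.
#' @param cohort Non-empty list of [vox_scan()] (or [vox_volume()]).
#' @param cfg A [train_config()].
#' @return An object of class `vox_model` with fields `net` (trained
#'   weights), `history` (per-epoch mean reconstruction loss) and `task`
#'   (`"autoencoder"`).
#' @export
pretrain_autoencoder <- function(net, cohort, cfg = train_config()) {
  stopifnot(inherits(net, "vox_network"))
  if (length(cohort) == 0) stop("cohort is empty")
  vols <- lapply(cohort, function(s) {
    if (inherits(s, "vox_scan")) s$volume$data
    else if (inherits(s, "vox_volume")) s$data
    else s
  })
  net <- apply_dropout_rate(net, cfg$dropout_rate)
  paths <- param_paths(net)
  nvox <- prod(net$input_shape)
  sigmoid_i <- length(net$layers)  # final activation layer (fused with the loss)
  withr::with_seed(cfg$seed, {
    state <- adam_init(net, paths)
    history <- numeric(0)
    t <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(vols))
      ep_loss <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        acc <- NULL
        for (ii in idx) {
          x <- vols[[ii]]
          fw <- net_forward(net, x, training = TRUE)
          xrec <- array(fw$out, dim = dim(x))
          ep_loss <- ep_loss + reconstruction_loss(x, xrec)
          g <- array((fw$out - array(x, dim = dim(fw$out))) / nvox,
                     dim = dim(fw$out))
          bw <- net_backward(net, fw$cache, g, from = sigmoid_i - 1L)
          acc <- grads_add(acc, bw$grads, paths)
        }
        acc <- grads_scale(acc, 1 / length(idx), paths)
        t <- t + 1L
        st <- adam_step(net, acc, state, paths, cfg, t)
        net <- st$net
        state <- st$state
      }
      history <- c(history, ep_loss / length(vols))
    }
    structure(list(net = net, history = data.frame(epoch = seq_along(history),
                                                   loss = history),
                   task = "autoencoder", config = cfg),
              class = "vox_model")
  })
}

# ---- supervised fine-tuning ---------------------------------------------

task_tag <- function(labels) paste(sort(unique(labels)), collapse = "-vs-")

#' Fine-tune a classifier on a labeled cohort
#'
#' Minimizes the two-class softmax cross-entropy plus the configured
#' penalties with Adam. When `cfg$augment` is on, each scan is replaced by
#' a random augmentation of itself in every epoch (on-the-fly, never
#' precomputed). History records the mean training loss and the training
#' accuracy per epoch (computed from the training-mode forward passes).
#'
#' @param net A classifier `vox_network` (fresh, pretrained-initialized or
#'   transfer-initialized).
#' @param cohort List of [vox_scan()] carrying exactly two distinct labels.
#' @param cfg A [train_config()].
#' @return A `vox_model` with fields `net`, `history`, `task`, `labels`
#'   (positive class first) and `config`.
#' @export
fine_tune <- function(net, cohort, cfg = train_config()) {
  stopifnot(inherits(net, "vox_network"))
  labels <- scan_labels(cohort)
  ulab <- unique(labels)
  if (length(ulab) != 2)
    stop("cohort must contain exactly 2 classes, got: ",
         paste(ulab, collapse = ", "))
  pos <- vox_positive_label(ulab)
  neg <- setdiff(ulab, pos)
  y <- ifelse(labels == pos, 1L, 2L)  # class index: 1 = positive
  net <- apply_dropout_rate(net, cfg$dropout_rate)
  paths <- param_paths(net)
  withr::with_seed(cfg$seed, {
    state <- adam_init(net, paths)
    hist_loss <- hist_acc <- numeric(0)
    t <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      vols <- lapply(cohort, function(s)
        if (cfg$augment) augment(s$volume, cfg$augment_params)$data
        else s$volume$data)
      ord <- sample(length(vols))
      ep_loss <- 0
      ep_correct <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        acc <- NULL
        for (ii in idx) {
          fw <- net_forward(net, vols[[ii]], training = TRUE)
          p <- softmax(fw$out)
          ep_loss <- ep_loss - log(max(p[y[ii]], 1e-12))
          ep_correct <- ep_correct + (which.max(p) == y[ii])
          g <- p
          g[y[ii]] <- g[y[ii]] - 1
          bw <- net_backward(net, fw$cache, g)
          acc <- grads_add(acc, bw$grads, paths)
        }
        acc <- grads_scale(acc, 1 / length(idx), paths)
        t <- t + 1L
        st <- adam_step(net, acc, state, paths, cfg, t)
        net <- st$net
        state <- st$state
      }
      hist_loss <- c(hist_loss, ep_loss / length(vols))
      hist_acc <- c(hist_acc, ep_correct / length(vols))
    }
    structure(list(net = net,
                   history = data.frame(epoch = seq_along(hist_loss),
                                        loss = hist_loss, accuracy = hist_acc),
                   task = task_tag(labels), labels = c(pos, neg), config = cfg),
              class = "vox_model")
  })
}

#' @export
print.vox_model <- function(x, ...) {
  cat(sprintf("<vox_model> task %s, %s parameters, %d epochs trained\n",
              x$task, format(count_parameters(x$net), big.mark = ","),
              nrow(x$history)))
  if (!is.null(x$history$loss))
    cat(sprintf("  final loss %.4f%s\n", utils::tail(x$history$loss, 1),
                if (!is.null(x$history$accuracy))
                  sprintf(", final training accuracy %.3f",
                          utils::tail(x$history$accuracy, 1)) else ""))
  invisible(x)
}

#' Class probabilities for volumes
#'
#' Inference-mode forward pass (dropout disabled); probabilities are the
#' softmax of the output logits.
#'
#' @param model A `vox_model` classifier.
#' @param scans A list of [vox_scan()]/[vox_volume()] or a single one.
#' @return Matrix with one row per input and columns named by the two
#'   class labels (positive class first).
#' @export
predict_proba <- function(model, scans) {
  stopifnot(inherits(model, "vox_model"))
  if (!is.list(scans) || inherits(scans, c("vox_scan", "vox_volume")))
    scans <- list(scans)
  out <- t(vapply(scans, function(s) {
    v <- if (inherits(s, "vox_scan")) s$volume else s
    softmax(net_forward(model$net, v)$out)
  }, numeric(2)))
  colnames(out) <- model$labels
  out
}

#' @export
predict_label.vox_model <- function(model, v, ...) {
  p <- predict_proba(model, v)
  model$labels[apply(p, 1, which.max)]
}

#' Classification accuracy of a model on labeled scans
#'
#' @param model A `vox_model` classifier.
#' @param scans List of [vox_scan()].
#' @return Fraction of correctly classified scans.
#' @export
model_accuracy <- function(model, scans) {
  pred <- predict_label(model, scans)
  mean(pred == scan_labels(scans))
}

# ---- transfer learning ---------------------------------------------------

#' Transfer the convolutional stack to a new task
#'
#' Initializes a fresh classifier for the target task with the source
#' model's convolutional (and inception) weights copied in bitwise; dense
#' and output layers are freshly initialized. All layers remain trainable
#' (the subsequent [fine_tune()] is joint, nothing is frozen).
#'
#' @param source A `vox_model` trained on the source task.
#' @param source_task,target_task Task tags; must differ.
#' @param seed Seed for the fresh dense-layer initialization.
#' @return A `vox_network` ready for [fine_tune()] on the target cohort.
#' @export
transfer_weights <- function(source, source_task = source$task, target_task,
                             seed = NULL) {
  stopifnot(inherits(source, "vox_model"))
  if (identical(source_task, target_task))
    stop("source and target tasks must differ")
  target <- build_network(source$net$variant, source$net$input_shape,
                          n_maps = source$net$n_maps, seed = seed)
  copy_encoder_weights(source$net, target)
}
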