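# Classification metrics, ROC/AUC, and the nested k-fold cross-validation
# protocol with inner grid search, independent repeats and a mechanical
# leakage audit.

#' Metrics from confusion counts
#'
#' Accuracy `(TP + TN) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and balanced accuracy `(SEN + SPE) / 2`. A ratio with a
#' zero denominator is reported as `NA` rather than 0. The alternative
#' specificity denominator `TN + FN` (which is in fact the negative
#' predictive value) is available for comparability with sources that
#' define it that way.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; `tp` may also be a named
#'   vector/list carrying all four.
#' @param spe_denominator `"fp"` for the standard `TN / (TN + FP)`;
#'   `"fn"` for `TN / (TN + FN)`.
#' @return A list of class `vox_metrics`: `acc`, `sen`, `spe`, `bac`.
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL,
                              spe_denominator = c("fp", "fn")) {
  spe_denominator <- match.arg(spe_denominator)
  if (is.list(tp) || length(tp) == 4) {
    cc <- as.list(tp)
    names(cc) <- tolower(names(cc))
    tn <- cc$tn; fp <- cc$fp; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- ratio(tp, tp + fn)
  spe <- if (spe_denominator == "fp") ratio(tn, tn + fp) else ratio(tn, tn + fn)
  structure(list(acc = (tp + tn) / total, sen = sen, spe = spe,
                 bac = (sen + spe) / 2),
            class = "vox_metrics")
}

#' @export
print.vox_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  SEN %.4f  SPE %.4f  BAC %.4f\n",
              x$acc, x$sen, x$spe, x$bac))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs whose scores are correctly ordered, with
#' ties counted one half. Curve points are computed at every distinct
#' score threshold and are monotone in both coordinates.
#'
#' @param labels Binary ground truth: logical, 0/1, or a factor/character
#'   vector with `positive` naming the positive class.
#' @param scores Numeric scores, higher meaning more positive.
#' @param positive Positive label when `labels` is not already binary.
#' @return List of class `vox_roc`: `auc` and a data frame `curve` with
#'   columns `threshold`, `fpr`, `tpr`.
#' @export
roc_auc <- function(labels, scores, positive = NULL) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (is.null(positive)) stop("specify the positive class for label vectors")
    y <- labels == positive
  } else y <- as.logical(labels)
  stopifnot(length(y) == length(scores))
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!y] >= t), 0)),
    tpr = c(0, vapply(thr, function(t) mean(scores[y] >= t), 0)))
  structure(list(auc = auc, curve = curve), class = "vox_roc")
}

#' @export
print.vox_roc <- function(x, ...) {
  cat(sprintf("<vox_roc> AUC %.4f (%d curve points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# regularization strength used to break inner-CV ties (stronger wins)
reg_strength <- function(hyper) {
  s <- 0
  for (nm in c("l1_weight", "l2_weight", "dropout_rate"))
    if (!is.null(hyper[[nm]])) s <- s + as.numeric(hyper[[nm]])
  s
}

#' Nested cross-validation with inner grid search
#'
#' For each independent repeat: a fresh stratified outer split into
#' `outer_k` folds; for each outer fold a grid search by stratified
#' `inner_k`-fold cross-validation on the outer-training portion (model
#' selection by mean inner validation accuracy, ties broken toward the
#' stronger regularization); the selected configuration is retrained on the
#' full outer-training portion and evaluated once on the held-out outer
#' test fold. Fold memberships are recorded so the absence of leakage can
#' be audited mechanically ([cv_audit()]).
#'
#' A model recipe is a list with two functions:
#' `fit(scans, hyper, seed)` returning any model object, and
#' `predict(model, scans)` returning the positive-class probability per
#' scan (label = positive when the score is at least 0.5).
#'
#' @param cohort List of [vox_scan()] with exactly two classes.
#' @param recipe Model recipe (see above), e.g. [recipe_majority()].
#' @param grid Data frame of hyperparameter combinations (one row each);
#'   a 0-row or NULL grid is an error.
#' @param outer_k,inner_k Fold counts.
#' @param repeats Independent repetitions with re-randomized folds.
#' @param seed Master seed; the whole report is reproducible from it.
#' @return A `vox_cv_report`: `results` (per repeat x fold metrics and the
#'   selected hyperparameters), `membership` (subject, repeat, outer fold,
#'   role), `summary` (mean and SD per metric).
#' @export
nested_cv <- function(cohort, recipe, grid, outer_k = 5L, inner_k = 5L,
                      repeats = 3L, seed = 1L) {
  labels <- scan_labels(cohort)
  ulab <- unique(labels)
  if (length(ulab) != 2) stop("cohort must contain exactly 2 classes")
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  if (min(table(labels)) < outer_k)
    stop("need at least outer_k subjects per class")
  pos <- vox_positive_label(ulab)
  ids <- scan_ids(cohort)
  results <- list()
  membership <- list()
  withr::with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      outer_fold <- stratified_folds(labels, outer_k)
      for (fold_i in seq_len(outer_k)) {
        test_idx <- which(outer_fold == fold_i)
        train_idx <- which(outer_fold != fold_i)
        # inner grid search confined to the outer-training portion
        inner_fold <- stratified_folds(labels[train_idx], inner_k)
        grid_acc <- numeric(nrow(grid))
        for (g in seq_len(nrow(grid))) {
          hyper <- as.list(grid[g, , drop = FALSE])
          accs <- vapply(seq_len(inner_k), function(f) {
            fit_idx <- train_idx[inner_fold != f]
            val_idx <- train_idx[inner_fold == f]
            m <- recipe$fit(cohort[fit_idx],
                            hyper, seed = sample.int(1e6, 1))
            sc <- recipe$predict(m, cohort[val_idx])
            pred <- ifelse(sc >= 0.5, pos, setdiff(ulab, pos))
            mean(pred == labels[val_idx])
          }, 0)
          grid_acc[g] <- mean(accs)
        }
        best <- which(grid_acc == max(grid_acc))
        if (length(best) > 1) {
          strength <- vapply(best, function(g)
            reg_strength(as.list(grid[g, , drop = FALSE])), 0)
          best <- best[which.max(strength)]
        }
        hyper <- as.list(grid[best, , drop = FALSE])
        model <- recipe$fit(cohort[train_idx], hyper, seed = sample.int(1e6, 1))
        sc <- recipe$predict(model, cohort[test_idx])
        truth <- labels[test_idx]
        pred <- ifelse(sc >= 0.5, pos, setdiff(ulab, pos))
        tp <- sum(pred == pos & truth == pos)
        tn <- sum(pred != pos & truth != pos)
        fp <- sum(pred == pos & truth != pos)
        fn <- sum(pred != pos & truth == pos)
        met <- confusion_metrics(tp, tn, fp, fn)
        auc <- if (length(unique(truth)) == 2)
          roc_auc(truth, sc, positive = pos)$auc else NA_real_
        results[[length(results) + 1L]] <- data.frame(
          repeat_i = rep_i, fold = fold_i,
          selected = paste(names(grid), unlist(hyper), sep = "=",
                           collapse = ";"),
          acc = met$acc, sen = met$sen, spe = met$spe, bac = met$bac,
          auc = auc)
        membership[[length(membership) + 1L]] <- data.frame(
          subject_id = ids[c(test_idx, train_idx)],
          repeat_i = rep_i, fold = fold_i,
          role = rep(c("test", "search"),
                     c(length(test_idx), length(train_idx))))
      }
    }
  })
  results <- do.call(rbind, results)
  membership <- do.call(rbind, membership)
  metric_cols <- c("acc", "sen", "spe", "bac", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(results[[m]], na.rm = TRUE), 0),
    sd = vapply(metric_cols, function(m) stats::sd(results[[m]], na.rm = TRUE), 0))
  structure(list(results = results, membership = membership,
                 summary = summary, positive = pos,
                 outer_k = outer_k, inner_k = inner_k,
                 repeats = repeats, seed = seed),
            class = "vox_cv_report")
}

#' @export
print.vox_cv_report <- function(x, ...) {
  cat(sprintf("<vox_cv_report> %d repeats x %d outer folds (positive class %s)\n",
              x$repeats, x$outer_k, x$positive))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s %.4f +/- %.4f\n", toupper(s$metric[i]), s$mean[i], s$sd[i]))
  invisible(x)
}

#' Audit a cross-validation report for leakage
#'
#' Verifies, from the recorded fold membership, that within every repeat
#' the outer test folds partition the cohort (each subject in exactly one
#' test fold) and that no subject ever appears both in an outer test fold
#' and in the hyperparameter-search data of the same fold.
#'
#' @param report A `vox_cv_report`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
cv_audit <- function(report) {
  m <- report$membership
  for (r in unique(m$repeat_i)) {
    mr <- m[m$repeat_i == r, ]
    test <- mr[mr$role == "test", ]
    counts <- table(test$subject_id)
    if (any(counts != 1))
      stop("repeat ", r, ": subjects in != 1 outer test fold: ",
           paste(names(counts)[counts != 1], collapse = ", "))
    if (!setequal(unique(mr$subject_id), test$subject_id))
      stop("repeat ", r, ": outer test folds do not cover the cohort")
    for (f in unique(mr$fold)) {
      tf <- test$subject_id[test$fold == f]
      sf <- mr$subject_id[mr$role == "search" & mr$fold == f]
      bad <- intersect(tf, sf)
      if (length(bad) > 0)
        stop("repeat ", r, " fold ", f, ": leakage for ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

# ---- model recipes -------------------------------------------------------

#' Baseline recipe: always predict the training majority class
#'
#' @return A recipe usable with [nested_cv()].
#' @export
recipe_majority <- function() {
  list(
    fit = function(scans, hyper, seed) {
      labs <- scan_labels(scans)
      names(which.max(table(labs)))
    },
    predict = function(model, scans) {
      pos <- vox_positive_label(unique(c(model, scan_labels(scans))))
      rep(if (model == pos) 1 else 0, length(scans))
    })
}

#' Recipe: threshold on the mean intensity inside a fixed mask
#'
#' Learns the decision threshold as the midpoint between the two class
#' means of the mask-mean statistic on the training scans; the score is a
#' logistic function of the (negated) distance to the threshold, so lower
#' mask intensity means a higher positive-class score.
#'
#' @param mask Logical 3D array.
#' @return A recipe usable with [nested_cv()].
#' @export
recipe_mask_mean <- function(mask) {
  stat <- function(scans)
    vapply(scans, function(s) mean(s$volume$data[mask]), 0)
  list(
    fit = function(scans, hyper, seed) {
      labs <- scan_labels(scans)
      pos <- vox_positive_label(unique(labs))
      x <- stat(scans)
      thr <- (mean(x[labs == pos]) + mean(x[labs != pos])) / 2
      scale <- stats::sd(x)
      if (!is.finite(scale) || scale == 0) scale <- 1
      list(thr = thr, scale = scale)
    },
    predict = function(model, scans)
      stats::plogis((model$thr - stat(scans)) / model$scale))
}

#' Recipe: volumetric CNN classifier
#'
#' Builds a fresh classifier (optionally from transferred weights) and
#' fine-tunes it; the grid row may carry `dropout_rate`, `l1_weight` and
#' `l2_weight`. Intended for small desk-scale cohorts; training cost grows
#' linearly in scans x epochs.
#'
#' @param variant Classifier variant for [build_network()].
#' @param input_shape Volume grid.
#' @param epochs Training epochs per fit.
#' @param source Optional source `vox_model` whose convolutional stack
#'   initializes every fit (transfer learning).
#' @param ... Further [train_config()] overrides.
#' @return A recipe usable with [nested_cv()].
#' @export
recipe_cnn <- function(variant = "cae_classifier", input_shape = c(24, 32, 24),
                       epochs = 20L, source = NULL, ...) {
  extra <- list(...)
  list(
    fit = function(scans, hyper, seed) {
      net <- if (is.null(source))
        build_network(variant, input_shape, seed = seed)
      else transfer_weights(source, target_task = task_tag(scan_labels(scans)),
                            seed = seed)
      args <- c(list(max_epochs = epochs, seed = seed), extra)
      for (nm in intersect(names(hyper), c("dropout_rate", "l1_weight", "l2_weight")))
        args[[nm]] <- hyper[[nm]]
      fine_tune(net, scans, do.call(train_config, args))
    },
    predict = function(model, scans) predict_proba(model, scans)[, 1])
}
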