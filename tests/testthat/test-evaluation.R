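test_that("confusion metrics match the closed forms", {
  m <- confusion_metrics(tp = 3, tn = 2, fp = 2, fn = 1)
  expect_equal(m$sen, 0.75)
  expect_equal(m$spe, 0.5)
  expect_equal(m$acc, 0.625)
  expect_equal(m$bac, 0.625)

  perfect <- confusion_metrics(tp = 5, tn = 7, fp = 0, fn = 0)
  expect_equal(unlist(perfect[c("acc", "sen", "spe", "bac")]),
               c(acc = 1, sen = 1, spe = 1, bac = 1))

  # balanced accuracy identity on published-scale sensitivity/specificity
  expect_equal((0.8855 + 0.8454) / 2, 0.86545)

  none <- confusion_metrics(tp = 0, tn = 3, fp = 1, fn = 0)
  expect_true(is.na(none$sen))
  expect_true(is.na(none$bac))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")

  # alternative (NPV-style) specificity denominator is available
  alt <- confusion_metrics(tp = 3, tn = 2, fp = 2, fn = 1,
                           spe_denominator = "fn")
  expect_equal(alt$spe, 2 / 3)
})

test_that("BAC identity holds on randomized counts", {
  withr::with_seed(60, {
    for (i in 1:25) {
      cc <- sample.int(30, 4)
      m <- confusion_metrics(cc[1], cc[2], cc[3], cc[4])
      expect_equal(m$bac, (m$sen + m$spe) / 2, tolerance = 1e-12)
      expect_gte(m$acc, 0)
      expect_lte(m$acc, 1)
    }
  })
})

test_that("AUC equals the pairwise-ordering oracle", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  pairwise_oracle <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- sample(4:50, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(runif(n), 2)  # rounded scores force ties
      expect_equal(roc_auc(y, s)$auc, pairwise_oracle(y, s), tolerance = 1e-12)
    }
  })
})

test_that("ROC curve points are monotone", {
  withr::with_seed(62, {
    y <- sample(0:1, 30, replace = TRUE)
    y[1:2] <- 0:1
    s <- round(runif(30), 1)
    r <- roc_auc(y, s)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_equal(utils::tail(r$curve$tpr, 1), 1)
    expect_equal(utils::tail(r$curve$fpr, 1), 1)
  })
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(63, {
    for (i in 1:5) {
      y <- c(0, 1, sample(0:1, 28, replace = TRUE))
      s <- round(rnorm(30), 1)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
    }
  })
})

make_mini_cohort <- function(n_ad = 12, n_nc = 8, seed = 70) {
  cfg <- desk_config(grid_shape = c(8, 8, 8), head_center = c(4.5, 4.5, 4.5),
                     head_radii = c(3.5, 3.5, 3.5),
                     lesion_ad_center = c(4.5, 4.5, 4.5),
                     lesion_ad_radii = c(1.5, 1.5, 1.5),
                     lesion_mci_center = c(3.5, 4.5, 4.5),
                     lesion_mci_radii = c(1.5, 1.5, 1.5))
  list(cfg = cfg,
       scans = generate_cohort(cfg, c(AD = n_ad, NC = n_nc), seed = seed))
}

test_that("nested CV partitions cleanly and is reproducible", {
  mini <- make_mini_cohort()
  grid <- data.frame(threshold_bias = c(0, 0))[1, , drop = FALSE]
  rec <- recipe_mask_mean(phantom_lesion_mask(mini$cfg, "AD"))
  rep1 <- nested_cv(mini$scans, rec, grid, outer_k = 4, inner_k = 3,
                    repeats = 2, seed = 5)
  expect_true(cv_audit(rep1))
  expect_equal(nrow(rep1$results), 8)  # 2 repeats x 4 folds
  rep2 <- nested_cv(mini$scans, rec, grid, outer_k = 4, inner_k = 3,
                    repeats = 2, seed = 5)
  expect_identical(rep1$results, rep2$results)
  expect_identical(rep1$membership, rep2$membership)

  # stratification: outer test folds deviate by at most one subject per class
  labs <- setNames(vapply(mini$scans, function(s) s$label, ""),
                   vapply(mini$scans, function(s) s$subject_id, ""))
  mem <- rep1$membership
  for (r in unique(mem$repeat_i)) for (f in unique(mem$fold)) {
    test_ids <- mem$subject_id[mem$repeat_i == r & mem$fold == f &
                                 mem$role == "test"]
    tab <- table(labs[test_ids])
    expect_lte(abs(tab[["AD"]] - 12 / 4), 1)
    expect_lte(abs(tab[["NC"]] - 8 / 4), 1)
  }
})

test_that("a majority-class recipe recovers the majority fraction", {
  mini <- make_mini_cohort(n_ad = 12, n_nc = 8)
  rep <- nested_cv(mini$scans, recipe_majority(),
                   data.frame(dummy = 0), outer_k = 4, inner_k = 3,
                   repeats = 3, seed = 8)
  expect_true(cv_audit(rep))
  acc <- rep$summary$mean[rep$summary$metric == "acc"]
  expect_equal(acc, 12 / 20, tolerance = 0.06)  # fold-rounding error only
})

test_that("an informative recipe beats the majority baseline on phantoms", {
  mini <- make_mini_cohort()
  rec <- recipe_mask_mean(phantom_lesion_mask(mini$cfg, "AD"))
  rep <- nested_cv(mini$scans, rec, data.frame(dummy = 0), outer_k = 4,
                   inner_k = 3, repeats = 2, seed = 9)
  acc <- rep$summary$mean[rep$summary$metric == "acc"]
  auc <- rep$summary$mean[rep$summary$metric == "auc"]
  expect_gt(acc, 0.9)
  expect_gt(auc, 0.95)
})

test_that("nested CV validates its inputs", {
  mini <- make_mini_cohort(n_ad = 3, n_nc = 3)
  expect_error(nested_cv(mini$scans, recipe_majority(), data.frame(d = 0),
                         outer_k = 5, repeats = 1, seed = 1), "at least")
  expect_error(nested_cv(mini$scans, recipe_majority(),
                         data.frame(), outer_k = 2, repeats = 1, seed = 1),
               "grid")
})
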