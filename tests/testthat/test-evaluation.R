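test_that("AUC matches closed forms, symmetry and the pairwise-ranking oracle", {
  expect_equal(compute_auc(c(-2, -1, 1, 2), c("NH", "NH", "HI", "HI")), 1)
  set.seed(23)
  scores <- rnorm(30)
  labels <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(compute_auc(scores, labels) + compute_auc(-scores, labels), 1)
  # exhaustive pairwise-ranking oracle
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(compute_auc(scores, labels), mean(pairs))
  # permutation oracle: shuffled labels average to 0.5
  perm <- replicate(1000, compute_auc(scores, sample(labels)))
  expect_lt(abs(mean(perm) - 0.5), 0.02)
  expect_error(compute_auc(scores, rep(TRUE, 30)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  for (i in 1:5) {
    scores <- rnorm(25)
    labels <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_auc(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("EER threshold balances the error rates", {
  # perfectly separated scores
  eer <- compute_eer(c(-2, -1, 1, 2), c("NH", "NH", "HI", "HI"))
  expect_equal(eer$accuracy, 1)
  # worked 4-point set: threshold 0, FPR = FNR = 0.5
  eer <- compute_eer(c(-2, -1, 1, 2), c("NH", "HI", "NH", "HI"))
  expect_equal(eer$threshold, 0)
  expect_equal(eer$accuracy, 0.5)
  # degenerate: all scores identical; boundary rate documented edge
  eer <- compute_eer(rep(1, 4), c("NH", "HI", "NH", "HI"))
  expect_true(eer$accuracy %in% c(0.5))
  expect_error(compute_eer(1:3, rep("HI", 3)), "both classes")
})

test_that("the EER threshold minimizes |FPR - FNR| over all candidates", {
  set.seed(25)
  for (i in 1:10) {
    scores <- round(rnorm(20), 1)
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    eer <- compute_eer(scores, labels)
    s <- sort(unique(scores))
    cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
    gaps <- sapply(cand, function(t)
      abs(sum(scores[!labels] > t) / sum(!labels) -
          sum(scores[labels] <= t) / sum(labels)))
    t_gap <- abs(sum(scores[!labels] > eer$threshold) / sum(!labels) -
                 sum(scores[labels] <= eer$threshold) / sum(labels))
    expect_equal(t_gap, min(gaps))
  }
})

test_that("stability index follows the Jaccard closed forms", {
  expect_equal(stability_index(list(c(1, 2), c(1, 2), c(1, 2))), 1)
  expect_equal(stability_index(list(1:2, 3:4, 5:6)), 0)
  expect_equal(stability_index(list(c(1, 2), c(2, 3))), 1 / 3)
  # two empty selections are identical selections
  expect_equal(stability_index(list(integer(0), integer(0))), 1)
  # permutation invariance in the fold order
  sets <- list(c(1, 2), c(2, 3), c(1, 3, 4))
  expect_equal(stability_index(sets), stability_index(rev(sets)))
  expect_true(stability_index(sets) >= 0 && stability_index(sets) <= 1)
})

test_that("LOOCV produces one fold per subject with coherent fields", {
  cv <- strong_effect_loocv()
  expect_equal(nrow(cv$folds), 6)
  expect_setequal(cv$folds$subject_id, sprintf("S%02d", 1:6))
  expect_true(all(cv$folds$pred_combined %in% c("HI", "NH")))
  expect_length(cv$selections, 6)
  expect_true(all(dim(cv$summary) == c(3, 5)))
  expect_true(all(cv$summary >= 0 & cv$summary <= 1))
  expect_error(loocv(simulate_cohort(n_hi = 1, n_nh = 3, seed = 1)),
               "2 subjects per class")
})

test_that("train-only dictionary scope excludes the test subject from the feature pool", {
  coh <- simulate_cohort(n_hi = 2, n_nh = 2, grid_shape = c(24, 24, 20),
                         blob_effect = 0.8, activation_effect = 0.8, seed = 33)
  full <- build_dictionary(coh)
  sub <- structure(list(subjects = coh$subjects[-1]), class = "hi_cohort")
  part <- build_dictionary(sub)
  # the held-out subject's ROIs are genuinely absent
  expect_lt(length(part$rois), length(full$rois))
  expect_false("S01" %in% vapply(part$rois, `[[`, character(1), "subject"))
  # and the loocv runs under that scope
  cv <- loocv(coh, hi_config(dictionary_scope = "train_only",
                             cube_side = 24L))
  expect_equal(nrow(cv$folds), 4)
})
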