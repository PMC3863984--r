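# Evaluation: ROC/AUC, equal-error-rate thresholds, the
# feature-selection stability index, and the leave-one-out
# cross-validation driver.

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC, computed as the Mann-Whitney
#' probability that a random positive outscores a random negative
#' (ties count 1/2).
#'
#' @param scores numeric decision scores.
#' @param labels logical (`TRUE` = positive/HI) or `"HI"`/`"NH"`.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  positive <- if (is.logical(labels)) labels else labels == "HI"
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop("both classes are required to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Equal-error-rate threshold and accuracy
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' scores plus sentinels) for the one minimizing `|FPR - FNR|` under
#' the rule "positive iff score > t"; ties take the lower threshold.
#' The EER accuracy is `1 - (FPR + FNR) / 2` at that threshold.
#'
#' @param scores numeric decision scores.
#' @param labels logical (`TRUE` = positive) or `"HI"`/`"NH"`.
#' @return list with `threshold` and `accuracy`.
#' @export
compute_eer <- function(scores, labels) {
  positive <- if (is.logical(labels)) labels else labels == "HI"
  if (!any(positive) || all(positive))
    stop("both classes are required to compute an EER", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  n1 <- sum(positive); n0 <- sum(!positive)
  fpr <- vapply(cand, function(t) sum(scores[!positive] > t) / n0, numeric(1))
  fnr <- vapply(cand, function(t) sum(scores[positive] <= t) / n1, numeric(1))
  i <- which.min(abs(fpr - fnr))
  list(threshold = cand[i], accuracy = 1 - (fpr[i] + fnr[i]) / 2)
}

#' Stability index of feature selections across folds
#'
#' Mean pairwise Jaccard similarity of the selected feature sets:
#' `Sim(s_i, s_j) = |s_i intersect s_j| / |s_i union s_j|`, averaged
#' over all pairs of folds. Two empty selections are identical
#' selections and score 1.
#'
#' @param selections list of >= 2 integer vectors.
#' @return index in `[0, 1]`.
#' @export
stability_index <- function(selections) {
  c_ <- length(selections)
  stopifnot(c_ >= 2)
  sim <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 1 else length(intersect(a, b)) / u
  }
  tot <- 0
  for (i in seq_len(c_ - 1)) for (j in (i + 1):c_)
    tot <- tot + sim(selections[[i]], selections[[j]])
  2 * tot / (c_ * (c_ - 1))
}

# classification summary for one arm given test-side scores,
# predictions and true labels (HI = positive)
arm_summary <- function(pred, truth, scores) {
  positive <- truth == "HI"
  data.frame(
    specificity = sum(pred[!positive] == "NH") / sum(!positive),
    sensitivity = sum(pred[positive] == "HI") / sum(positive),
    accuracy = mean(pred == truth),
    auc = compute_auc(scores, positive),
    eer = compute_eer(scores, positive)$accuracy)
}

# full-cohort fMRI design: dictionary, merged matrix + sedation columns
fmri_design <- function(cohort, config) {
  dict <- build_dictionary(cohort, config$top_fraction, config$mask)
  mat <- feature_matrix(cohort, dict)
  merged <- merge_rois(mat, config$inconsistency_cutoff,
                       config$inconsistency_depth)
  sed <- encode_sedation(vapply(cohort$subjects, `[[`, numeric(1), "sedation"))
  M <- cbind(merged$matrix, sed)
  list(dict = dict, matrix = M, membership = merged$membership,
       n_roi_columns = ncol(merged$matrix))
}

# per-(cube, orientation) feature index + similarity adjacency,
# computed once and reused across folds
smri_precompute <- function(cohort, config) {
  banks <- lapply(cohort$subjects, function(s)
    extract_subject_features(s$anatomical, s$subject_id, s$group,
                             config$cube_side, config$sift))
  bank <- bind_banks(banks)
  keys <- group_key(bank$meta)
  groups <- lapply(unique(keys), function(k) {
    idx <- which(keys == k)
    sub <- subset_bank(bank, keys == k)
    list(key = k, idx = idx, adj = similarity_adjacency(sub, config$thr))
  })
  names(groups) <- unique(keys)
  list(bank = bank, groups = groups)
}

# train the sMRI arm for one fold using the precomputed adjacency;
# returns the model plus Csum for every subject (in-sample for the
# training subjects, out-of-sample for the rest)
smri_fold <- function(pre, train_ids, config) {
  bank <- pre$bank
  subj <- unique(bank$meta[, c("subject_id", "group")])
  train_subj <- subj[subj$subject_id %in% train_ids, ]
  n_p <- sum(train_subj$group == "HI")
  n_c <- sum(train_subj$group == "NH")
  support_min <- if (is.null(config$support_min)) n_p + n_c else config$support_min
  vec <- sift_vectors(bank)
  csum <- setNames(numeric(nrow(subj)), subj$subject_id)
  classifiers <- list()
  for (g in pre$groups) {
    tr <- bank$meta$subject_id[g$idx] %in% train_ids
    if (!any(tr)) next
    adj_tr <- g$adj[tr, tr, drop = FALSE]
    is_p <- bank$meta$group[g$idx][tr] == "HI"
    n_sp <- drop(adj_tr %*% is_p)
    n_sc <- drop(adj_tr %*% !is_p)
    lik <- vapply(seq_along(n_sp), function(i)
      likelihood_score(n_sp[i], n_sc[i], n_p, n_c, support_min,
                       config$alpha), numeric(1))
    labels <- label_feature(lik, config$eps_l)
    clf <- train_group_classifier(vec[g$idx[tr], , drop = FALSE], labels,
                                  config$cost_smri)
    classifiers[[g$key]] <- clf
    pred <- predict_group_classifier(clf, vec[g$idx, , drop = FALSE])
    agg <- tapply(pred, bank$meta$subject_id[g$idx], sum)
    csum[names(agg)] <- csum[names(agg)] + agg
  }
  train_pos <- train_subj$group == "HI"
  eps_s <- balanced_threshold(csum[train_subj$subject_id], train_pos)
  list(classifiers = classifiers, csum = csum, eps_s = eps_s)
}

#' Leave-one-out cross-validation of the two-layer classifier
#'
#' For each fold, the held-out subject is removed from all training
#' computations: the structural arm is retrained (likelihood scores,
#' per-cube classifiers, and `eps_s` equalizing training FPR/FNR), the
#' functional arm reruns feature selection and SVM training
#' (`eps_f = 0`), and the second layer is refit on in-sample training
#' scores (`eps_i = 0`). Under the default `dictionary_scope =
#' "all_subjects"` the ROI dictionary (a feature pool, not a trained
#' quantity) is built once from all subjects; `"train_only"` rebuilds
#' it per fold from the training subjects.
#'
#' The summary reports, per classifier, the specificity, sensitivity
#' and accuracy of the training-derived thresholds applied to the test
#' subjects, the AUC of the test scores, and the EER accuracy computed
#' purely from the test scores.
#'
#' @param cohort an `hi_cohort` with >= 2 subjects per group.
#' @param config an [hi_config()].
#' @param verbose print fold progress.
#' @return an `hi_loocv`: `folds` (per-subject scores and
#'   predictions), `summary` (3 x 5 metric table), `stability`
#'   (feature-selection stability index), `selections`,
#'   `importance` (per-feature importance over folds).
#' @export
loocv <- function(cohort, config = hi_config(), verbose = FALSE) {
  groups <- cohort_groups(cohort)
  if (sum(groups == "HI") < 2 || sum(groups == "NH") < 2)
    stop("LOOCV needs at least 2 subjects per class", call. = FALSE)
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  n <- length(ids)
  pre <- smri_precompute(cohort, config)
  all_scope <- config$dictionary_scope == "all_subjects"
  design <- if (all_scope) fmri_design(cohort, config) else NULL

  folds <- vector("list", n)
  selections <- vector("list", n)
  weights <- vector("list", n)
  n_features <- if (all_scope) ncol(design$matrix) else NA_integer_
  for (f in seq_len(n)) {
    if (verbose) message("fold ", f, "/", n, " (test ", ids[f], ")")
    train_ids <- ids[-f]
    sm <- smri_fold(pre, train_ids, config)
    if (all_scope) {
      M <- design$matrix
      fm <- train_fmri(M[-f, , drop = FALSE], groups[-f] == "HI",
                       cost = config$cost_fmri,
                       stop_after = config$cfs_stop_after,
                       correlation = config$correlation,
                       max_expansions = config$cfs_max_expansions)
      f_train <- vapply(seq_len(n)[-f], function(i)
        score_row_fmri(M[i, ], fm), numeric(1))
      f_test <- score_row_fmri(M[f, ], fm)
    } else {
      sub_cohort <- structure(list(subjects = cohort$subjects[-f]),
                              class = "hi_cohort")
      dsg <- fmri_design(sub_cohort, config)
      fm <- train_fmri(dsg$matrix, groups[-f] == "HI",
                       cost = config$cost_fmri,
                       stop_after = config$cfs_stop_after,
                       correlation = config$correlation,
                       max_expansions = config$cfs_max_expansions)
      f_train <- vapply(seq_len(n - 1), function(i)
        score_row_fmri(dsg$matrix[i, ], fm), numeric(1))
      vec_test <- vectorize_subject(cohort$subjects[[f]], dsg$dict)
      row_test <- c(vapply(dsg$membership, function(m) mean(vec_test[m]),
                           numeric(1)),
                    encode_sedation(cohort$subjects[[f]]$sedation))
      f_test <- score_row_fmri(row_test, fm)
    }
    sl <- train_second_layer(
      cbind(sm$csum[train_ids], f_train), groups[-f] == "HI",
      cost = config$cost_second)
    csum_test <- sm$csum[ids[f]]
    y_test <- score_combined(csum_test, f_test, sl)
    folds[[f]] <- data.frame(
      fold = f, subject_id = ids[f], group = groups[f],
      csum = unname(csum_test), fmri_score = f_test, y = y_test,
      eps_s = sm$eps_s,
      pred_smri = ifelse(csum_test > sm$eps_s, "HI", "NH"),
      pred_fmri = ifelse(f_test >= fm$eps_f, "HI", "NH"),
      pred_combined = classify_combined(y_test))
    selections[[f]] <- fm$selected
    weights[[f]] <- fm$w
  }
  folds <- do.call(rbind, folds)
  summary <- rbind(
    sMRI = arm_summary(folds$pred_smri, folds$group, folds$csum),
    fMRI = arm_summary(folds$pred_fmri, folds$group, folds$fmri_score),
    `sMRI + fMRI` = arm_summary(folds$pred_combined, folds$group, folds$y))
  structure(list(folds = folds, summary = summary,
                 stability = stability_index(selections),
                 selections = selections,
                 importance = if (all_scope)
                   feature_importance(selections, weights, n_features)
                 else NULL,
                 config = config),
            class = "hi_loocv")
}

#' @export
print.hi_loocv <- function(x, digits = 2, ...) {
  cat(sprintf("Leave-one-out cross-validation (%d folds)\n", nrow(x$folds)))
  print(round(x$summary, digits))
  cat(sprintf("Feature-selection stability index: %.3f\n", x$stability))
  invisible(x)
}

#' @export
summary.hi_loocv <- function(object, ...) {
  print(object, ...)
  invisible(object$summary)
}

#' ROC curves of the three classifiers from a LOOCV result
#'
#' @param x an `hi_loocv`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hi_loocv <- function(x, ...) {
  roc_pts <- function(scores, positive) {
    ts <- c(Inf, sort(unique(scores), decreasing = TRUE))
    t(vapply(ts, function(t) c(
      fpr = sum(scores[!positive] >= t) / sum(!positive),
      tpr = sum(scores[positive] >= t) / sum(positive)), numeric(2)))
  }
  pos <- x$folds$group == "HI"
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  cols <- c("steelblue", "darkorange", "black")
  scores <- list(x$folds$csum, x$folds$fmri_score, x$folds$y)
  for (i in 1:3) {
    p <- roc_pts(scores[[i]], pos)
    graphics::lines(p[, 1], p[, 2], col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", c("sMRI", "fMRI", "sMRI + fMRI"),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
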