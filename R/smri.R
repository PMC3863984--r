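# Structural arm: likelihood-based labeling of training features per
# (cube, orientation) group, one-vs-rest linear SVM feature
# classifiers, and the per-subject Csum score.

group_key <- function(meta) paste(meta$cube_id, meta$orientation, sep = "|")

#' Evaluate and label the SIFT features of a training bank
#'
#' For every feature, the similar-feature set is computed among the
#' other features of the same cube and slice orientation, the
#' likelihood score is the per-brain normalized patient/healthy
#' log-frequency ratio of that set, and the score is thresholded into
#' a 3-class label (+1 patient, 0 noise, -1 healthy).
#'
#' @param bank training `sift_bank` whose `meta$group` is `"HI"` or
#'   `"NH"` for every feature.
#' @param thr [similarity_thresholds()].
#' @param eps_l labeling threshold (default 0.9).
#' @param support_min minimum similar-set size; default `NULL` means
#'   number of patient brains + number of healthy brains.
#' @param alpha likelihood smoothing pseudocount.
#' @return the bank with `meta$likelihood` and `meta$label` columns
#'   added.
#' @export
evaluate_features <- function(bank, thr = similarity_thresholds(),
                              eps_l = 0.9, support_min = NULL, alpha = 1) {
  meta <- bank$meta
  if (!nrow(meta)) stop("empty feature bank", call. = FALSE)
  subj <- unique(meta[, c("subject_id", "group")])
  n_p <- sum(subj$group == "HI")
  n_c <- sum(subj$group == "NH")
  if (n_p < 1 || n_c < 1)
    stop("training bank needs features from both groups", call. = FALSE)
  if (is.null(support_min)) support_min <- n_p + n_c
  lik <- numeric(nrow(meta))
  keys <- group_key(meta)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    sub <- list(meta = meta[idx, , drop = FALSE],
                desc = bank$desc[idx, , drop = FALSE])
    adj <- similarity_adjacency(sub, thr)
    is_p <- sub$meta$group == "HI"
    n_sp <- adj %*% is_p
    n_sc <- adj %*% (!is_p)
    lik[idx] <- vapply(seq_along(idx), function(i)
      likelihood_score(n_sp[i], n_sc[i], n_p, n_c, support_min, alpha),
      numeric(1))
  }
  bank$meta$likelihood <- lik
  bank$meta$label <- label_feature(lik, eps_l)
  bank
}

# one-vs-rest multiclass linear SVM over standardized 133-vectors;
# degenerate groups fall back to a constant predictor
train_group_classifier <- function(X, labels, cost = 1) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    return(list(type = "constant", value = if (length(classes)) classes else 0L))
  fit <- std_fit(X)
  Xs <- std_apply(X, fit)
  machines <- lapply(classes, function(k)
    linear_svm_fit(Xs, labels == k, cost = cost))
  if (any(vapply(machines, is.null, logical(1)))) {
    # SVM could not be fit (e.g. duplicated rows across classes)
    tab <- table(labels)
    return(list(type = "constant",
                value = as.integer(names(tab)[which.max(tab)])))
  }
  list(type = "svm", classes = classes, std = fit, machines = machines)
}

predict_group_classifier <- function(clf, X) {
  n <- nrow(X)
  if (clf$type == "constant") return(rep(clf$value, n))
  Xs <- std_apply(X, clf$std)
  dec <- vapply(clf$machines, function(m) drop(Xs %*% m$w) + m$b,
                numeric(n))
  dec <- matrix(dec, nrow = n)
  clf$classes[max.col(dec, ties.method = "first")]
}

#' Train the structural (sMRI) arm
#'
#' Labels the training bank by likelihood score and trains one linear
#' 3-class feature classifier per (cube, orientation) group on the
#' 133-number feature vectors. Groups whose training features carry a
#' single label class get a constant predictor. The subject decision
#' threshold `eps_s` is chosen on the training subjects' Csum scores
#' so that training false positive and false negative rates are as
#' close to equal as possible (smallest such threshold; candidate
#' thresholds are midpoints between consecutive distinct scores).
#'
#' @param bank training `sift_bank` (groups `"HI"`/`"NH"`).
#' @param thr,eps_l,support_min,alpha see [evaluate_features()].
#' @param cost SVM regularization constant for the feature classifiers.
#' @return an `smri_model`: per-group classifiers, thresholds, and the
#'   training subjects' Csum scores.
#' @export
train_smri <- function(bank, thr = similarity_thresholds(), eps_l = 0.9,
                       support_min = NULL, alpha = 1, cost = 1) {
  bank <- evaluate_features(bank, thr, eps_l, support_min, alpha)
  keys <- group_key(bank$meta)
  vec <- sift_vectors(bank)
  classifiers <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    classifiers[[k]] <- train_group_classifier(
      vec[idx, , drop = FALSE], bank$meta$label[idx], cost)
  }
  model <- structure(list(classifiers = classifiers, thr = thr,
                          eps_l = eps_l, alpha = alpha,
                          support_min = support_min, cost = cost),
                     class = "smri_model")
  subj <- unique(bank$meta[, c("subject_id", "group")])
  csum <- vapply(subj$subject_id, function(sid)
    score_bank_smri(subset_bank(bank, bank$meta$subject_id == sid), model),
    numeric(1))
  model$train_scores <- data.frame(subject_id = subj$subject_id,
                                   group = subj$group, csum = csum)
  model$eps_s <- balanced_threshold(csum, subj$group == "HI")
  model
}

subset_bank <- function(bank, keep) {
  structure(list(meta = bank$meta[keep, , drop = FALSE],
                 desc = bank$desc[keep, , drop = FALSE]),
            class = "sift_bank")
}

#' Score a subject's feature bank with a trained sMRI model
#'
#' Every feature is predicted by the classifier of its (cube,
#' orientation) group; Csum is the sum of predicted labels (+1
#' patient, -1 healthy, 0 noise). Features falling in groups without a
#' trained classifier are skipped. The subject is called HI when
#' `Csum > eps_s` (strict).
#'
#' @param bank the subject's `sift_bank`.
#' @param model an `smri_model`.
#' @return scalar Csum score.
#' @export
score_bank_smri <- function(bank, model) {
  if (!nrow(bank$meta)) return(0)
  keys <- group_key(bank$meta)
  vec <- sift_vectors(bank)
  csum <- 0
  for (k in unique(keys)) {
    clf <- model$classifiers[[k]]
    if (is.null(clf)) next
    idx <- which(keys == k)
    csum <- csum + sum(predict_group_classifier(clf, vec[idx, , drop = FALSE]))
  }
  csum
}

#' Score a structural volume with a trained sMRI model
#'
#' @param volume 3D array on the training grid.
#' @param model an `smri_model`.
#' @param cube_side cube side used at training.
#' @param params [sift_params()] used at training.
#' @return scalar Csum.
#' @export
score_subject_smri <- function(volume, model, cube_side = 20L,
                               params = sift_params()) {
  bank <- extract_subject_features(volume, "new", "unknown", cube_side, params)
  score_bank_smri(bank, model)
}

# smallest threshold t minimizing |FPR - FNR| for the rule
# "positive iff score > t"; candidates are midpoints between distinct
# sorted scores plus sentinels outside the score range
balanced_threshold <- function(scores, positive) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  gap <- vapply(cand, function(t) {
    fpr <- sum(scores[!positive] > t) / n_neg
    fnr <- sum(scores[positive] <= t) / n_pos
    abs(fpr - fnr)
  }, numeric(1))
  cand[which.min(gap)]  # which.min takes the first (= smallest) on ties
}
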