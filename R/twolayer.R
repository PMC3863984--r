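# Second layer: a linear SVM (C = 1) over the 2D score space
# (Csum, fMRI_score). Scores are used raw (no standardization).

#' Train the second-layer score fusion
#'
#' Fits a linear SVM with `C = 1` in the two-dimensional space of
#' first-layer scores. Training scores are the in-sample scores of the
#' first-layer classifiers applied to their own training set.
#'
#' @param scores numeric matrix or data frame with two columns
#'   (Csum, fMRI score), one row per training subject.
#' @param labels logical (`TRUE` = HI) or `"HI"`/`"NH"` vector.
#' @param cost SVM C constant (default 1).
#' @return a `second_layer_model`: `w1`, `w2`, `bias`, `eps_i`.
#' @export
train_second_layer <- function(scores, labels, cost = 1) {
  X <- as.matrix(scores)
  stopifnot(ncol(X) == 2L)
  positive <- if (is.logical(labels)) labels else labels == "HI"
  if (!any(positive) || all(positive))
    stop("second-layer training needs both classes", call. = FALSE)
  svm <- linear_svm_fit(X, positive, cost = cost)
  if (is.null(svm))
    stop("second-layer SVM training failed", call. = FALSE)
  structure(list(w1 = unname(svm$w[1]), w2 = unname(svm$w[2]),
                 bias = unname(svm$b), eps_i = 0, cost = cost),
            class = "second_layer_model")
}

#' Combined decision score and classification
#'
#' `y = w1 * Csum + w2 * fMRI_score + bias`; the subject is called HI
#' when `y >= eps_i` (inclusive; default 0).
#'
#' @param csum structural score(s).
#' @param fmri_score functional score(s).
#' @param model a `second_layer_model`.
#' @return numeric decision score(s).
#' @export
score_combined <- function(csum, fmri_score, model) {
  model$w1 * csum + model$w2 * fmri_score + model$bias
}

#' @rdname score_combined
#' @param y combined decision score(s).
#' @param eps_i decision threshold (inclusive).
#' @return `classify_combined`: `"HI"`/`"NH"` label(s).
#' @export
classify_combined <- function(y, eps_i = 0) {
  ifelse(y >= eps_i, "HI", "NH")
}
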