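#' Fit the two-layer sMRI + fMRI classifier
#'
#' Trains the full model on a cohort: the structural arm (SIFT
#' likelihood labeling and per-cube one-vs-rest linear SVMs producing
#' the Csum score, with `eps_s` balancing training error rates), the
#' functional arm (bag-of-words ROI dictionary, merged columns,
#' sedation encoding, CFS feature selection, linear SVM), and the
#' second-layer linear SVM (C = 1) over the two in-sample score
#' columns.
#'
#' @param cohort an `hi_cohort` with at least one subject per group.
#' @param config an [hi_config()].
#' @return an `hi_classifier` with components `smri`, `fmri`
#'   (dictionary, merged-column membership, selected features,
#'   weights), `second` (w1, w2, bias), `scores` (training scores) and
#'   `config`. Methods: [predict.hi_classifier()], `print`, `summary`,
#'   `coef`.
#' @export
hi_classifier <- function(cohort, config = hi_config()) {
  groups <- cohort_groups(cohort)
  if (!any(groups == "HI") || !any(groups == "NH"))
    stop("training cohort needs both groups", call. = FALSE)
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")

  banks <- lapply(cohort$subjects, function(s)
    extract_subject_features(s$anatomical, s$subject_id, s$group,
                             config$cube_side, config$sift))
  smri <- train_smri(bind_banks(banks), config$thr, config$eps_l,
                     config$support_min, config$alpha, config$cost_smri)

  design <- fmri_design(cohort, config)
  fmri <- train_fmri(design$matrix, groups == "HI",
                     cost = config$cost_fmri,
                     stop_after = config$cfs_stop_after,
                     correlation = config$correlation,
                     max_expansions = config$cfs_max_expansions)
  f_scores <- vapply(seq_along(ids), function(i)
    score_row_fmri(design$matrix[i, ], fmri), numeric(1))
  csum <- smri$train_scores$csum[match(ids, smri$train_scores$subject_id)]

  second <- train_second_layer(cbind(csum, f_scores), groups == "HI",
                               cost = config$cost_second)
  scores <- data.frame(subject_id = ids, group = groups, csum = csum,
                       fmri_score = f_scores,
                       y = score_combined(csum, f_scores, second))
  structure(list(smri = smri, fmri = fmri,
                 dictionary = design$dict,
                 membership = design$membership,
                 n_roi_columns = design$n_roi_columns,
                 second = second, scores = scores, config = config),
            class = "hi_classifier")
}

# full feature row (merged ROI means + sedation one-hot) for a subject
subject_feature_row <- function(subject, object) {
  vec <- vectorize_subject(subject, object$dictionary)
  c(vapply(object$membership, function(m) mean(vec[m]), numeric(1)),
    encode_sedation(subject$sedation))
}

#' Predict group membership for new subjects
#'
#' @param object an `hi_classifier`.
#' @param newdata an `hi_cohort` or a single subject (list with
#'   `anatomical`, `contrasts`, `sedation`); defaults to the training
#'   cohort scores.
#' @param ... unused.
#' @return data frame with per-subject `csum`, `fmri_score`, combined
#'   score `y`, and the three classifiers' labels.
#' @export
predict.hi_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    sc <- object$scores
  } else {
    subjects <- if (inherits(newdata, "hi_cohort")) newdata$subjects
                else list(newdata)
    sc <- do.call(rbind, lapply(subjects, function(s) {
      csum <- score_subject_smri(s$anatomical, object$smri,
                                 object$config$cube_side,
                                 object$config$sift)
      fs <- score_row_fmri(subject_feature_row(s, object), object$fmri)
      data.frame(subject_id = if (!is.null(s$subject_id)) s$subject_id else NA,
                 group = if (!is.null(s$group)) s$group else NA,
                 csum = csum, fmri_score = fs,
                 y = score_combined(csum, fs, object$second))
    }))
  }
  sc$pred_smri <- ifelse(sc$csum > object$smri$eps_s, "HI", "NH")
  sc$pred_fmri <- ifelse(sc$fmri_score >= object$fmri$eps_f, "HI", "NH")
  sc$pred_combined <- classify_combined(sc$y, object$second$eps_i)
  sc
}

#' @export
coef.hi_classifier <- function(object, ...) {
  c(w1 = object$second$w1, w2 = object$second$w2, bias = object$second$bias)
}

#' @export
print.hi_classifier <- function(x, ...) {
  n <- nrow(x$scores)
  cat("Two-layer sMRI + fMRI classifier\n")
  cat(sprintf("  trained on %d subjects (%d HI, %d NH)\n", n,
              sum(x$scores$group == "HI"), sum(x$scores$group == "NH")))
  cat(sprintf("  sMRI: %d cube/orientation classifiers, eps_s = %.3g\n",
              length(x$smri$classifiers), x$smri$eps_s))
  cat(sprintf("  fMRI: dictionary of %d ROIs -> %d merged columns, %d selected\n",
              length(x$dictionary$rois), x$n_roi_columns,
              length(x$fmri$selected)))
  cat(sprintf("  second layer: y = %.3g * Csum + %.3g * fMRI_score + %.3g\n",
              x$second$w1, x$second$w2, x$second$bias))
  invisible(x)
}

#' @export
summary.hi_classifier <- function(object, ...) {
  print(object)
  pr <- predict(object)
  acc <- mean(pr$pred_combined == pr$group)
  cat(sprintf("  in-sample combined accuracy: %.3f\n", acc))
  invisible(object)
}
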