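#' Grid search over similarity and likelihood thresholds
#'
#' Optional reproduction of the threshold tuning protocol: every
#' combination of the orientation threshold grid (pi/4, 2pi/4, 3pi/4),
#' the appearance threshold grid (0.30-0.50) and the likelihood
#' threshold grid (0.1-1.2) is evaluated by the LOOCV accuracy of the
#' structural arm alone. Not run by default anywhere; the package
#' defaults are the chosen values (pi/2, 0.45, 0.9).
#'
#' @param cohort an `hi_cohort`.
#' @param config an [hi_config()] (its other settings are kept).
#' @param eps_o_grid,eps_a_grid,eps_l_grid candidate values.
#' @param verbose print progress.
#' @return data frame with one row per combination and its LOOCV
#'   sMRI-arm accuracy and AUC.
#' @export
tune_smri_thresholds <- function(cohort, config = hi_config(),
                                 eps_o_grid = c(pi / 4, 2 * pi / 4, 3 * pi / 4),
                                 eps_a_grid = c(0.30, 0.35, 0.40, 0.45, 0.50),
                                 eps_l_grid = seq(0.1, 1.2, by = 0.1),
                                 verbose = FALSE) {
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  groups <- cohort_groups(cohort)
  out <- NULL
  for (eo in eps_o_grid) for (ea in eps_a_grid) {
    cfg <- config
    cfg$thr <- similarity_thresholds(config$thr$eps_x, config$thr$eps_sigma,
                                     eo, ea)
    pre <- smri_precompute(cohort, cfg)
    for (el in eps_l_grid) {
      cfg$eps_l <- el
      preds <- character(length(ids))
      scores <- numeric(length(ids))
      for (f in seq_along(ids)) {
        sm <- smri_fold(pre, ids[-f], cfg)
        scores[f] <- sm$csum[ids[f]]
        preds[f] <- if (scores[f] > sm$eps_s) "HI" else "NH"
      }
      out <- rbind(out, data.frame(
        eps_o = eo, eps_a = ea, eps_l = el,
        accuracy = mean(preds == groups),
        auc = compute_auc(scores, groups == "HI")))
      if (verbose)
        message(sprintf("eps_o=%.3f eps_a=%.2f eps_l=%.1f acc=%.3f",
                        eo, ea, el, out$accuracy[nrow(out)]))
    }
  }
  out
}
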