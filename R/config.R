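#' Configuration for the two-layer classifier
#'
#' Collects every tunable threshold of the pipeline with the defaults
#' used throughout: similarity thresholds (0.5, 2/3, pi/2, 0.45),
#' likelihood labeling threshold 0.9, top-5% ROI selection,
#' inconsistency cutoff 0.01 (depth 2), CFS stop rule of 5
#' consecutive non-improving expansions, and C = 1 linear SVMs.
#'
#' @param cube_side cube side in voxels.
#' @param thr [similarity_thresholds()].
#' @param eps_l likelihood labeling threshold.
#' @param support_min minimum similar-set size (`NULL` = number of
#'   training brains).
#' @param alpha likelihood smoothing pseudocount.
#' @param sift [sift_params()].
#' @param top_fraction extreme-voxel fraction per sign class.
#' @param inconsistency_cutoff dendrogram cut level.
#' @param inconsistency_depth levels in the inconsistency statistic.
#' @param correlation CFS correlation measure.
#' @param cfs_stop_after CFS stop rule.
#' @param cfs_max_expansions CFS expansion cap.
#' @param cost_smri,cost_fmri,cost_second SVM C constants for the
#'   feature classifiers, the fMRI classifier and the second layer.
#' @param dictionary_scope `"all_subjects"` (the ROI dictionary is
#'   built from every available subject, including a held-out test
#'   subject) or `"train_only"` (dictionary rebuilt from the training
#'   subjects of each fold).
#' @param mask optional logical array restricting extreme-voxel
#'   selection.
#' @return list of class `hi_config`.
#' @export
hi_config <- function(cube_side = 20L,
                      thr = similarity_thresholds(),
                      eps_l = 0.9, support_min = NULL, alpha = 1,
                      sift = sift_params(),
                      top_fraction = 0.05,
                      inconsistency_cutoff = 0.01,
                      inconsistency_depth = 2L,
                      correlation = "pearson",
                      cfs_stop_after = 5L,
                      cfs_max_expansions = 200L,
                      cost_smri = 1, cost_fmri = 1, cost_second = 1,
                      dictionary_scope = c("all_subjects", "train_only"),
                      mask = NULL) {
  structure(list(cube_side = as.integer(cube_side), thr = thr,
                 eps_l = eps_l, support_min = support_min, alpha = alpha,
                 sift = sift, top_fraction = top_fraction,
                 inconsistency_cutoff = inconsistency_cutoff,
                 inconsistency_depth = as.integer(inconsistency_depth),
                 correlation = correlation,
                 cfs_stop_after = as.integer(cfs_stop_after),
                 cfs_max_expansions = as.integer(cfs_max_expansions),
                 cost_smri = cost_smri, cost_fmri = cost_fmri,
                 cost_second = cost_second,
                 dictionary_scope = match.arg(dictionary_scope),
                 mask = mask),
            class = "hi_config")
}
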