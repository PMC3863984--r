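# Functional arm: top-5% extreme-voxel selection, 26-connected ROI
# extraction, bag-of-words dictionary and vectorization, redundant-ROI
# merging by average-linkage clustering with an inconsistency cut,
# sedation encoding, and the linear fMRI classifier.

#' Select extreme voxels of a contrast map
#'
#' Positive voxels are ranked decreasingly and negative voxels
#' increasingly by value; the top `ceiling(fraction * n)` of each sign
#' class is returned (computed over non-zero voxels of that sign, or
#' over `mask` when given). Ties at the cutoff are broken by voxel
#' index order.
#'
#' @param map 3D numeric array.
#' @param fraction fraction of each sign class to keep (default 0.05).
#' @param mask optional logical array restricting the eligible voxels.
#' @return data frame with `voxel` (linear index into `map`) and
#'   `sign` (`+1` / `-1`).
#' @export
select_extreme_voxels <- function(map, fraction = 0.05, mask = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  vals <- as.vector(map)
  elig <- if (is.null(mask)) rep(TRUE, length(vals)) else as.vector(mask)
  pos <- which(elig & vals > 0)
  neg <- which(elig & vals < 0)
  take <- function(idx, decreasing) {
    if (!length(idx)) return(integer(0))
    k <- ceiling(fraction * length(idx))
    v <- vals[idx]
    ord <- order(if (decreasing) -v else v, idx)
    idx[ord[seq_len(k)]]
  }
  p <- take(pos, TRUE)
  n <- take(neg, FALSE)
  data.frame(voxel = c(p, n),
             sign = rep(c(1L, -1L), c(length(p), length(n))))
}

# 26-connectivity components over a set of linear voxel indices;
# returns an integer component id per voxel (union-find)
label_components_26 <- function(voxels, grid_shape) {
  n <- length(voxels)
  if (!n) return(integer(0))
  grid_shape <- check_grid_shape(grid_shape)
  coords <- arrayInd(voxels, grid_shape)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  for (o in seq_len(nrow(off))) {
    nb <- coords + matrix(off[o, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
          nb[, 3] >= 1 & nb[, 3] <= nz
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * nx * ny + (nb[ok, 2] - 1) * nx + nb[ok, 1]
    hit <- match(nb_lin, voxels)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Extract connected ROIs from selected extreme voxels
#'
#' Positive and negative voxels are componentized separately under
#' 26-connectivity, so an ROI never mixes signs (mixing would cancel
#' the signal when averaging).
#'
#' @param selected data frame from [select_extreme_voxels()].
#' @param grid_shape shape of the source map.
#' @param contrast contrast name.
#' @param subject source subject id.
#' @return list of ROIs; each is a list with `voxels` (linear
#'   indices), `sign`, `contrast`, `subject`.
#' @export
connected_rois <- function(selected, grid_shape, contrast = NA_character_,
                           subject = NA_character_) {
  out <- list()
  for (sg in c(1L, -1L)) {
    vox <- selected$voxel[selected$sign == sg]
    if (!length(vox)) next
    vox <- sort(vox)
    comp <- label_components_26(vox, grid_shape)
    for (ci in sort(unique(comp)))
      out[[length(out) + 1L]] <- list(voxels = vox[comp == ci], sign = sg,
                                      contrast = contrast, subject = subject)
  }
  out
}

#' Build the bag-of-words ROI dictionary
#'
#' Concatenates the ROIs of all subjects in a fixed, recorded order:
#' contrast (canonical order), then subject order, then component
#' order. Every ROI becomes one dictionary word / feature column.
#'
#' @param cohort an `hi_cohort` (or list of subjects with `contrasts`).
#' @param fraction top fraction per sign class.
#' @param mask optional logical array.
#' @return an `roi_dictionary`: list with `rois` (ordered list),
#'   `grid_shape`, `contrast_sizes`.
#' @export
build_dictionary <- function(cohort, fraction = 0.05, mask = NULL) {
  subjects <- cohort$subjects
  grid_shape <- dim(subjects[[1]]$contrasts[[1]])
  rois <- list()
  sizes <- integer(0)
  for (cn in CONTRAST_NAMES) {
    n0 <- length(rois)
    for (s in subjects) {
      sel <- select_extreme_voxels(s$contrasts[[cn]], fraction, mask)
      rr <- connected_rois(sel, grid_shape, cn, s$subject_id)
      rois <- c(rois, rr)
    }
    sizes[cn] <- length(rois) - n0
  }
  structure(list(rois = rois, grid_shape = grid_shape,
                 contrast_sizes = sizes),
            class = "roi_dictionary")
}

#' Vectorize a subject's contrast maps against a dictionary
#'
#' Entry j is the mean value of the subject's matching contrast map
#' over dictionary ROI j's voxels.
#'
#' @param subject a subject (list with `contrasts`).
#' @param dict an `roi_dictionary`.
#' @return numeric vector of length `length(dict$rois)`.
#' @export
vectorize_subject <- function(subject, dict) {
  if (!identical(dim(subject$contrasts[[1]]), as.integer(dict$grid_shape)) &&
      !identical(as.integer(dim(subject$contrasts[[1]])),
                 as.integer(dict$grid_shape)))
    stop("subject maps are not on the dictionary grid", call. = FALSE)
  vapply(dict$rois, function(r) mean(subject$contrasts[[r$contrast]][r$voxels]),
         numeric(1))
}

#' Subjects-by-ROI feature matrix
#'
#' @param cohort an `hi_cohort`.
#' @param dict an `roi_dictionary`.
#' @return numeric matrix, one row per subject.
#' @export
feature_matrix <- function(cohort, dict) {
  m <- t(vapply(cohort$subjects, vectorize_subject,
                numeric(length(dict$rois)), dict = dict))
  rownames(m) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  m
}

# Dendrogram inconsistency coefficient. For each link the statistic
# (h - mean) / sd is computed over the heights of the link and its
# descendants down to `depth - 1` levels, with leaves counting as
# zero-height joins. Under this convention a join of two identical
# columns (height 0) has coefficient 0 while a join of two distinct
# singleton columns has coefficient 2/sqrt(3) ~ 1.155 regardless of
# its height, so cutting anywhere in (0, 1.15) separates exact
# redundancy from genuine structure.
inconsistency <- function(hc, depth = 2L) {
  nlink <- nrow(hc$merge)
  heights_below <- function(link, d) {
    hs <- hc$height[link]
    if (d > 1) {
      for (ch in hc$merge[link, ]) {
        hs <- c(hs, if (ch > 0) heights_below(ch, d - 1) else 0)
      }
    }
    hs
  }
  vapply(seq_len(nlink), function(l) {
    hs <- heights_below(l, depth)
    if (length(hs) < 2) return(0)
    s <- stats::sd(hs)
    if (s < .Machine$double.eps) 0 else (hc$height[l] - mean(hs)) / s
  }, numeric(1))
}

# cluster assignment: cut every link whose subtree contains a link with
# inconsistency >= cutoff; maximal consistent subtrees become clusters
cut_inconsistent <- function(hc, cutoff, depth = 2L) {
  n <- length(hc$order)
  inc <- inconsistency(hc, depth)
  nlink <- nrow(hc$merge)
  subtree_ok <- logical(nlink)
  for (l in seq_len(nlink)) {  # merge rows are ordered children-first
    ok <- inc[l] < cutoff
    for (ch in hc$merge[l, ]) if (ch > 0) ok <- ok && subtree_ok[ch]
    subtree_ok[l] <- ok
  }
  cl <- integer(n)
  next_id <- 0L
  leaves_of <- function(link) {
    out <- integer(0)
    for (ch in hc$merge[link, ])
      out <- c(out, if (ch < 0) -ch else leaves_of(ch))
    out
  }
  assign_node <- function(link) {
    if (subtree_ok[link]) {
      next_id <<- next_id + 1L
      cl[leaves_of(link)] <<- next_id
    } else {
      for (ch in hc$merge[link, ]) {
        if (ch > 0) assign_node(ch)
        else {
          next_id <<- next_id + 1L
          cl[-ch] <<- next_id
        }
      }
    }
  }
  if (nlink) assign_node(nlink) else cl[1] <- 1L
  # renumber in first-appearance (column) order for determinism
  match(cl, unique(cl))
}

#' Merge redundant ROI columns by hierarchical clustering
#'
#' Columns (ROIs) are clustered by average linkage on the Euclidean
#' distance across the subject dimension; the tree is cut where the
#' dendrogram inconsistency coefficient reaches `cutoff` (default
#' 0.01, depth 2), and each cluster is replaced by the mean of its
#' member columns.
#'
#' @param mat subjects-by-ROI matrix.
#' @param cutoff inconsistency cutoff.
#' @param depth inconsistency depth.
#' @return list with `matrix` (merged columns), `membership` (list of
#'   original column indices per merged column).
#' @export
merge_rois <- function(mat, cutoff = 0.01, depth = 2L) {
  p <- ncol(mat)
  if (p < 2L)
    return(list(matrix = mat, membership = as.list(seq_len(p))))
  hc <- stats::hclust(stats::dist(t(mat)), method = "average")
  cl <- cut_inconsistent(hc, cutoff, depth)
  k <- max(cl)
  merged <- vapply(seq_len(k), function(g)
    rowMeans(mat[, cl == g, drop = FALSE]), numeric(nrow(mat)))
  merged <- matrix(merged, nrow = nrow(mat))
  list(matrix = merged,
       membership = lapply(seq_len(k), function(g) which(cl == g)))
}

#' One-hot encoding of the sedation method
#'
#' @param method integer in `{1, 2, 3}` (vectorized).
#' @return for a single method, a length-3 0/1 vector; for several, a
#'   matrix with one row per method.
#' @export
encode_sedation <- function(method) {
  if (any(!method %in% 1:3)) stop("unknown sedation method", call. = FALSE)
  m <- diag(3)[method, , drop = FALSE]
  colnames(m) <- paste0("sedation", 1:3)
  if (length(method) == 1L) drop(m) else m
}

#' Train the functional (fMRI) arm
#'
#' Runs correlation-based feature selection on the merged-ROI +
#' sedation matrix, then fits a linear SVM on the selected,
#' standardized features. The decision score of a subject is the
#' signed SVM decision value; the subject is called HI when
#' `score >= eps_f` (inclusive; default `eps_f = 0`).
#'
#' @param mat numeric matrix (subjects x features), merged ROI columns
#'   plus sedation columns.
#' @param labels logical or `"HI"`/`"NH"` vector (positives = HI).
#' @param cost SVM C constant (default 1).
#' @param stop_after CFS stop rule: consecutive non-improving
#'   expansions.
#' @param correlation `"pearson"` or `"spearman"` for the CFS merit.
#' @param max_expansions safety cap on CFS expansions.
#' @return an `fmri_model`: selected feature ids, standardization
#'   statistics, weights and intercept.
#' @export
train_fmri <- function(mat, labels, cost = 1, stop_after = 5L,
                       correlation = "pearson", max_expansions = 200L) {
  positive <- if (is.logical(labels)) labels else labels == "HI"
  sel <- cfs_search(mat, positive, stop_after = stop_after,
                    correlation = correlation,
                    max_expansions = max_expansions)
  if (!length(sel)) sel <- which.max(abs_cor(mat, positive, correlation))
  X <- mat[, sel, drop = FALSE]
  fit <- std_fit(X)
  svm <- linear_svm_fit(std_apply(X, fit), positive, cost = cost)
  if (is.null(svm))
    stop("fMRI SVM training failed (degenerate input)", call. = FALSE)
  structure(list(selected = sel, std = fit, w = svm$w, b = svm$b,
                 eps_f = 0, correlation = correlation),
            class = "fmri_model")
}

#' Score a subject's feature row with a trained fMRI model
#'
#' @param row numeric vector over the full (merged + sedation) feature
#'   space used at training.
#' @param model an `fmri_model`.
#' @return scalar decision score.
#' @export
score_row_fmri <- function(row, model) {
  if (max(model$selected) > length(row))
    stop("feature row does not cover the selected features", call. = FALSE)
  x <- (row[model$selected] - model$std$mu) / model$std$sd
  sum(x * model$w) + model$b
}

#' Feature importance across cross-validation folds
#'
#' `I_f = sum_i sigma_i * |w_if|` where `sigma_i` indicates whether
#' feature f was selected in fold i and `w_if` is its SVM weight in
#' that fold. A merged ROI inherits the importance of its joint
#' feature.
#'
#' @param selections list (one per fold) of selected feature ids.
#' @param weights list (one per fold) of weight vectors aligned with
#'   the corresponding selection.
#' @param n_features total number of features.
#' @return numeric importance per feature.
#' @export
feature_importance <- function(selections, weights, n_features) {
  imp <- numeric(n_features)
  for (i in seq_along(selections)) {
    sel <- selections[[i]]
    if (!length(sel)) next
    imp[sel] <- imp[sel] + abs(weights[[i]])
  }
  imp
}
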