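# Similarity metrics between SIFT features, similar-feature sets and
# likelihood scoring. A "feature" here is a list (or one-row bank view)
# with fields x (3-vector), sigma, orient, appearance (128-vector).

#' Similarity thresholds for SIFT feature comparison
#'
#' Defaults: location 0.5 (in units of the query feature's scale),
#' scale 2/3 (absolute log-ratio), orientation pi/2 (circular
#' difference), appearance 0.45 (Euclidean distance between
#' unit-normalized descriptors).
#'
#' @param eps_x,eps_sigma,eps_o,eps_a positive thresholds; `eps_o`
#'   must not exceed pi.
#' @return list of class `similarity_thresholds`.
#' @export
similarity_thresholds <- function(eps_x = 0.5, eps_sigma = 2 / 3,
                                  eps_o = pi / 2, eps_a = 0.45) {
  stopifnot(eps_x > 0, eps_sigma > 0, eps_o > 0, eps_o <= pi, eps_a > 0)
  structure(list(eps_x = eps_x, eps_sigma = eps_sigma,
                 eps_o = eps_o, eps_a = eps_a),
            class = "similarity_thresholds")
}

as_feature <- function(bank, i) {
  list(x = c(bank$meta$x[i], bank$meta$y[i], bank$meta$z[i]),
       sigma = bank$meta$sigma[i], orient = bank$meta$orient[i],
       appearance = bank$desc[i, ])
}

#' Pairwise difference metrics between two SIFT features
#'
#' * `delta_x`: Euclidean distance between centers, normalized by the
#'   query feature's scale (asymmetric in its arguments).
#' * `delta_sigma`: absolute log scale ratio `|ln(sigma_j / sigma_i)|`.
#' * `delta_o`: circular orientation difference in `[0, pi]`.
#' * `delta_a`: Euclidean distance between appearance descriptors.
#'
#' @param fi,fj features: lists with `x` (3-vector), `sigma`, `orient`,
#'   `appearance` (128-vector).
#' @return scalar difference.
#' @export
delta_x <- function(fi, fj) {
  if (fi$sigma <= 0) stop("query feature scale must be positive", call. = FALSE)
  sqrt(sum((fi$x - fj$x)^2)) / fi$sigma
}

#' @rdname delta_x
#' @export
delta_sigma <- function(fi, fj) {
  if (fi$sigma <= 0 || fj$sigma <= 0)
    stop("feature scales must be positive", call. = FALSE)
  abs(log(fj$sigma / fi$sigma))
}

#' @rdname delta_x
#' @export
delta_o <- function(fi, fj) {
  d <- abs(fi$orient - fj$orient)
  min(d, 2 * pi - d)
}

#' @rdname delta_x
#' @export
delta_a <- function(fi, fj) {
  sqrt(sum((fi$appearance - fj$appearance)^2))
}

#' Similar feature set of a query feature
#'
#' Returns the candidates whose four difference metrics are all
#' strictly below their thresholds. Candidates are expected to come
#' from the same cube and slice orientation as the query (similarity
#' is only ever evaluated within a cube).
#'
#' @param fi query feature (list with `x`, `sigma`, `orient`,
#'   `appearance`).
#' @param candidates a `sift_bank` of candidate features.
#' @param thr [similarity_thresholds()].
#' @return integer indices into `candidates` of the similar features.
#' @export
similar_set <- function(fi, candidates, thr = similarity_thresholds()) {
  n <- nrow(candidates$meta)
  if (!n) return(integer(0))
  dx <- sqrt((candidates$meta$x - fi$x[1])^2 +
             (candidates$meta$y - fi$x[2])^2 +
             (candidates$meta$z - fi$x[3])^2) / fi$sigma
  ds <- abs(log(candidates$meta$sigma / fi$sigma))
  do_ <- abs(candidates$meta$orient - fi$orient)
  do_ <- pmin(do_, 2 * pi - do_)
  da <- sqrt(rowSums(sweep(candidates$desc, 2L, fi$appearance, "-")^2))
  which(dx < thr$eps_x & ds < thr$eps_sigma &
        do_ < thr$eps_o & da < thr$eps_a)
}

# n x n logical adjacency: [i, j] TRUE when feature j is similar to
# query feature i (asymmetric because delta_x is normalized by the
# query's scale). Diagonal is FALSE: a feature is never its own
# evidence when counting set members.
similarity_adjacency <- function(bank, thr = similarity_thresholds()) {
  n <- nrow(bank$meta)
  if (!n) return(matrix(FALSE, 0, 0))
  xs <- cbind(bank$meta$x, bank$meta$y, bank$meta$z)
  d2 <- as.matrix(stats::dist(xs))^2
  dx_ok <- sqrt(d2) / bank$meta$sigma < thr$eps_x      # rows = query i
  ls <- log(bank$meta$sigma)
  ds_ok <- abs(outer(ls, ls, function(a, b) b - a)) < thr$eps_sigma
  od <- abs(outer(bank$meta$orient, bank$meta$orient, "-"))
  do_ok <- pmin(od, 2 * pi - od) < thr$eps_o
  g2 <- tcrossprod(bank$desc)
  nrm <- rowSums(bank$desc^2)
  ad2 <- pmax(outer(nrm, nrm, "+") - 2 * g2, 0)
  da_ok <- sqrt(ad2) < thr$eps_a
  adj <- dx_ok & ds_ok & do_ok & da_ok
  diag(adj) <- FALSE
  adj
}

#' Likelihood score of a SIFT feature
#'
#' Log-ratio of the (per-brain normalized) frequency of the feature's
#' similar set among patient versus healthy training features:
#' `L = ln[ (|S ∩ P| / N_P) / (|S ∩ C| / N_C) ]` when the similar set
#' holds at least `support_min` features, else 0. Additive smoothing
#' (pseudocount `alpha` on both intersection counts and both brain
#' counts) guards empty intersections; `alpha = 0` reproduces the raw
#' ratio with infinite values capped at +-50.
#'
#' @param n_sp count of similar features from patient brains.
#' @param n_sc count of similar features from healthy brains.
#' @param n_p number of patient brains in the training set.
#' @param n_c number of healthy brains in the training set.
#' @param support_min minimum similar-set size for a nonzero score
#'   (default `n_p + n_c`: about one similar feature per training
#'   brain).
#' @param alpha smoothing pseudocount (default 1).
#' @return scalar likelihood score.
#' @export
likelihood_score <- function(n_sp, n_sc, n_p, n_c,
                             support_min = n_p + n_c, alpha = 1) {
  if (n_p < 1 || n_c < 1)
    stop("both patient and healthy brains are required", call. = FALSE)
  if (n_sp + n_sc < support_min) return(0)
  l <- log(((n_sp + alpha) / (n_p + alpha)) /
           ((n_sc + alpha) / (n_c + alpha)))
  max(min(l, 50), -50)
}

#' Label a feature from its likelihood score
#'
#' `+1` (patient feature) when the score exceeds `eps_l`, `-1`
#' (healthy feature) when it is below `-eps_l`, `0` (noise) otherwise.
#'
#' @param l likelihood score (vectorized).
#' @param eps_l positive labeling threshold (default 0.9).
#' @return integer label(s) in `{-1, 0, 1}`.
#' @export
label_feature <- function(l, eps_l = 0.9) {
  stopifnot(eps_l > 0)
  ifelse(l > eps_l, 1L, ifelse(l < -eps_l, -1L, 0L))
}
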