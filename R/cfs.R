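# Correlation-based feature selection: subset merit and best-first
# search over subsets (greedy hill-climbing with a backtracking open
# list), stopping after a fixed number of consecutive non-improving
# expansions.

# |correlation| of each feature with the +-1 class; zero-variance
# features get correlation 0
abs_cor <- function(mat, positive, correlation = "pearson") {
  y <- ifelse(positive, 1, -1)
  r <- suppressWarnings(stats::cor(mat, y, method = correlation))
  r[!is.finite(r)] <- 0
  abs(drop(r))
}

abs_cor_matrix <- function(mat, correlation = "pearson") {
  r <- suppressWarnings(stats::cor(mat, method = correlation))
  r[!is.finite(r)] <- 0
  abs(r)
}

merit_from_sums <- function(k, s_cf, s_ff) {
  if (k == 0L) return(0)
  s_cf / sqrt(k + 2 * s_ff)
}

#' CFS merit of a feature subset
#'
#' `M_S = k * rbar_cf / sqrt(k + k (k - 1) * rbar_ff)` where `rbar_cf`
#' is the mean absolute feature-class correlation over the subset and
#' `rbar_ff` the mean absolute feature-feature correlation over
#' distinct pairs. Class labels are encoded +-1 and correlations are
#' Pearson by default (the features are continuous region means);
#' zero-variance features contribute correlation 0.
#'
#' @param subset integer feature ids (non-empty).
#' @param labels logical (`TRUE` = HI) or `"HI"`/`"NH"` vector.
#' @param mat subjects-by-features matrix.
#' @param correlation `"pearson"` or `"spearman"`.
#' @return scalar merit.
#' @export
cfs_merit <- function(subset, labels, mat, correlation = "pearson") {
  stopifnot(length(subset) >= 1)
  positive <- if (is.logical(labels)) labels else labels == "HI"
  rcf <- abs_cor(mat[, subset, drop = FALSE], positive, correlation)
  k <- length(subset)
  s_ff <- if (k > 1) {
    rff <- abs_cor_matrix(mat[, subset, drop = FALSE], correlation)
    (sum(rff) - k) / 2  # sum over distinct pairs (diagonal is 1)
  } else 0
  merit_from_sums(k, sum(rcf), s_ff)
}

#' Best-first CFS subset search
#'
#' Starts from the empty set; successors of a node flip one feature in
#' or out. An open list ordered by merit provides the backtracking
#' facility: the best unexpanded node is always expanded next. The
#' search stops after `stop_after` consecutive expansions that fail to
#' improve the best merit found (or at `max_expansions`), and returns
#' the best-merit subset.
#'
#' @param mat subjects-by-features matrix.
#' @param labels logical (`TRUE` = HI) or `"HI"`/`"NH"` vector.
#' @param stop_after consecutive non-improving expansions before
#'   stopping (default 5).
#' @param correlation correlation measure for the merit.
#' @param max_expansions safety cap on the number of node expansions.
#' @return integer vector of selected feature ids (possibly empty).
#' @export
cfs_search <- function(mat, labels, stop_after = 5L,
                       correlation = "pearson", max_expansions = 200L) {
  positive <- if (is.logical(labels)) labels else labels == "HI"
  p <- ncol(mat)
  if (p < 1L) return(integer(0))
  rcf <- abs_cor(mat, positive, correlation)
  rff <- abs_cor_matrix(mat, correlation)
  diag(rff) <- 0
  key_of <- function(sel) paste0("s", paste(sel, collapse = ","))
  seen <- new.env(parent = emptyenv())
  # open list: subsets with their merits; expanded nodes are masked out
  open_sel <- list(integer(0))
  open_merit <- 0
  open_live <- TRUE
  seen[[key_of(integer(0))]] <- TRUE
  best_sel <- integer(0)
  best_merit <- 0
  stall <- 0L
  expansions <- 0L
  while (expansions < max_expansions) {
    cand_merit <- ifelse(open_live, open_merit, -Inf)
    pick <- which.max(cand_merit)
    if (!is.finite(cand_merit[pick])) break
    open_live[pick] <- FALSE
    expansions <- expansions + 1L
    sel <- open_sel[[pick]]
    k <- length(sel)
    in_sel <- logical(p); in_sel[sel] <- TRUE
    s_cf <- sum(rcf[sel])
    s_ff <- if (k > 1) sum(rff[sel, sel]) / 2 else 0
    cross <- if (k) colSums(rff[sel, , drop = FALSE]) else numeric(p)
    # merits of all p one-flip successors, vectorized
    m_all <- numeric(p)
    add <- !in_sel
    if (any(add)) {
      s2 <- s_cf + rcf[add]
      f2 <- s_ff + cross[add]
      m_all[add] <- s2 / sqrt((k + 1) + 2 * f2)
    }
    if (any(in_sel)) {
      if (k == 1L) m_all[in_sel] <- 0
      else {
        s2 <- s_cf - rcf[in_sel]
        f2 <- s_ff - cross[in_sel]
        m_all[in_sel] <- s2 / sqrt((k - 1) + 2 * f2)
      }
    }
    children <- lapply(seq_len(p), function(f)
      if (in_sel[f]) sel[sel != f] else sort(c(sel, f)))
    keys <- vapply(children, key_of, character(1))
    new <- !vapply(keys, function(kk) !is.null(seen[[kk]]), logical(1))
    for (kk in keys[new]) seen[[kk]] <- TRUE
    if (any(new)) {
      open_sel <- c(open_sel, children[new])
      open_merit <- c(open_merit, m_all[new])
      open_live <- c(open_live, rep(TRUE, sum(new)))
    }
    improved <- any(new) && max(m_all[new]) > best_merit + 1e-12
    if (improved) {
      best <- which(new)[which.max(m_all[new])]
      best_merit <- m_all[best]
      best_sel <- children[[best]]
    }
    stall <- if (improved) 0L else stall + 1L
    if (stall >= stop_after) break
  }
  best_sel
}
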