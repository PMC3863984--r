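#' @keywords internal
"_PACKAGE"

# Canonical contrast names, in dictionary column order.
CONTRAST_NAMES <- c("speech_vs_silence", "speech_vs_tones", "tones_vs_silence")

ORIENTATIONS <- c("axial", "coronal", "sagittal")

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_grid_shape <- function(grid_shape) {
  if (length(grid_shape) != 3L || any(!is.finite(grid_shape)) ||
      any(grid_shape < 1) || any(grid_shape != round(grid_shape)))
    stop_config("grid_shape must be 3 positive integers")
  as.integer(grid_shape)
}

# Column standardization with guarded zero-variance columns.
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mu, "-"), 2L, fit$sd, "/")
}

#' Fit a binary linear SVM and return an explicit weight vector
#'
#' Thin wrapper around [e1071::svm()] (linear kernel, C-classification)
#' that returns the primal weight vector and intercept oriented so that
#' the decision value `X %*% w + b` is larger for the positive class.
#'
#' @param X numeric matrix (rows = samples).
#' @param positive logical vector, `TRUE` for the positive class.
#' @param cost SVM regularization constant C.
#' @return list with elements `w` (weights) and `b` (intercept), or
#'   `NULL` when the SVM cannot be fit (degenerate input).
#' @keywords internal
linear_svm_fit <- function(X, positive, cost = 1) {
  X <- as.matrix(X)
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("pos", "neg"))
  if (length(unique(y)) < 2L) return(NULL)
  m <- tryCatch(
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
               type = "C-classification"),
    error = function(e) NULL)
  if (is.null(m)) return(NULL)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  d <- drop(X %*% w) + b
  # libsvm's decision sign depends on training label order; normalize it
  if (mean(d[positive]) < mean(d[!positive])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}
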