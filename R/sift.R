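# 2D SIFT: difference-of-Gaussian scale-space extrema with orientation
# assignment and the 4x4x8 gradient-histogram descriptor. Operates on
# small slice images, so Gaussian filtering is done with cached
# reflected-boundary convolution matrices (two matrix products per blur).

.blur_cache <- new.env(parent = emptyenv())

blur_matrix <- function(n, sigma) {
  key <- sprintf("%d_%.5f", n, sigma)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + x
    idx[idx < 1] <- 2 - idx[idx < 1]        # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    idx <- pmin(pmax(idx, 1L), n)
    for (t in seq_along(idx))
      M[i, idx[t]] <- M[i, idx[t]] + k[t]
  }
  .blur_cache[[key]] <- M
  M
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blur_matrix(nrow(img), sigma) %*% img %*% t(blur_matrix(ncol(img), sigma))
}

#' SIFT detector parameters
#'
#' Detector thresholds are exposed because the slices this package
#' analyses are small (20 x 20 pixels for interior cubes) and may need
#' a more permissive contrast threshold than photographic defaults.
#'
#' @param contrast_thresh minimum absolute difference-of-Gaussian
#'   response at a keypoint (images are used at their native intensity
#'   scale; for volumes normalized to roughly unit range the default is
#'   permissive enough for low-contrast anatomy).
#' @param edge_thresh principal-curvature ratio bound used to discard
#'   edge-like responses (larger = more permissive).
#' @param n_octaves number of scale-space octaves.
#' @param n_scales difference-of-Gaussian levels per octave on which
#'   extrema are detected.
#' @param sigma0 base scale of the first level, in pixels.
#' @param min_size smallest image side on which detection is attempted.
#' @return list of class `sift_params`.
#' @export
sift_params <- function(contrast_thresh = 0.01, edge_thresh = 10,
                        n_octaves = 2L, n_scales = 3L, sigma0 = 1.6,
                        min_size = 8L) {
  structure(list(contrast_thresh = contrast_thresh, edge_thresh = edge_thresh,
                 n_octaves = as.integer(n_octaves),
                 n_scales = as.integer(n_scales),
                 sigma0 = sigma0, min_size = as.integer(min_size)),
            class = "sift_params")
}

# strict 26-neighborhood extrema of a DoG stack, interior pixels only
detect_extrema <- function(D, thresh) {
  n1 <- dim(D)[1]; n2 <- dim(D)[2]; nl <- dim(D)[3]
  if (n1 < 3 || n2 < 3) return(NULL)
  ir <- 2:(n1 - 1); ic <- 2:(n2 - 1)
  found <- NULL
  for (l in 2:(nl - 1)) {
    C <- D[ir, ic, l]
    hot <- abs(C) > 0.8 * thresh
    if (!any(hot)) next
    ismax <- hot & (C > 0)
    ismin <- hot & (C < 0)
    for (dl in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (dl == 0 && dr == 0 && dc == 0) next
      N <- D[ir + dr, ic + dc, l + dl]
      ismax <- ismax & (C > N)
      ismin <- ismin & (C < N)
    }
    sel <- which(ismax | ismin, arr.ind = TRUE)
    if (nrow(sel))
      found <- rbind(found, cbind(sel[, 1] + 1L, sel[, 2] + 1L, l))
  }
  found
}

# quadratic sub-pixel refinement of an extremum; returns clamped offset
# (row, col, level) and the interpolated response
refine_extremum <- function(D, r, c, l) {
  g <- c((D[r + 1, c, l] - D[r - 1, c, l]) / 2,
         (D[r, c + 1, l] - D[r, c - 1, l]) / 2,
         (D[r, c, l + 1] - D[r, c, l - 1]) / 2)
  v <- D[r, c, l]
  H <- matrix(0, 3, 3)
  H[1, 1] <- D[r + 1, c, l] + D[r - 1, c, l] - 2 * v
  H[2, 2] <- D[r, c + 1, l] + D[r, c - 1, l] - 2 * v
  H[3, 3] <- D[r, c, l + 1] + D[r, c, l - 1] - 2 * v
  H[1, 2] <- H[2, 1] <- (D[r + 1, c + 1, l] - D[r + 1, c - 1, l] -
                         D[r - 1, c + 1, l] + D[r - 1, c - 1, l]) / 4
  H[1, 3] <- H[3, 1] <- (D[r + 1, c, l + 1] - D[r + 1, c, l - 1] -
                         D[r - 1, c, l + 1] + D[r - 1, c, l - 1]) / 4
  H[2, 3] <- H[3, 2] <- (D[r, c + 1, l + 1] - D[r, c + 1, l - 1] -
                         D[r, c - 1, l + 1] + D[r, c - 1, l - 1]) / 4
  off <- tryCatch(drop(-solve(H, g)), error = function(e) c(0, 0, 0))
  off[!is.finite(off)] <- 0
  off <- pmax(pmin(off, 0.5), -0.5)
  list(off = off, val = v + 0.5 * sum(g * off))
}

edge_like <- function(D, r, c, l, edge_thresh) {
  v <- D[r, c, l]
  dxx <- D[r + 1, c, l] + D[r - 1, c, l] - 2 * v
  dyy <- D[r, c + 1, l] + D[r, c - 1, l] - 2 * v
  dxy <- (D[r + 1, c + 1, l] - D[r + 1, c - 1, l] -
          D[r - 1, c + 1, l] + D[r - 1, c - 1, l]) / 4
  tr <- dxx + dyy
  dt <- dxx * dyy - dxy^2
  dt <= 0 || tr^2 / dt >= (edge_thresh + 1)^2 / edge_thresh
}

# dominant gradient orientation in [0, 2*pi)
assign_orientation <- function(gmag, gdir, r0, c0, sigma_local) {
  n1 <- nrow(gmag); n2 <- ncol(gmag)
  ws <- 1.5 * sigma_local
  rad <- max(2L, as.integer(round(3 * ws)))
  rr <- max(2L, as.integer(round(r0)) - rad):min(n1 - 1L, as.integer(round(r0)) + rad)
  cc <- max(2L, as.integer(round(c0)) - rad):min(n2 - 1L, as.integer(round(c0)) + rad)
  if (!length(rr) || !length(cc)) return(0)
  dr <- rr - r0; dc <- cc - c0
  d2 <- outer(dr^2, dc^2, "+")
  w <- gmag[rr, cc, drop = FALSE] * exp(-d2 / (2 * ws^2))
  ang <- gdir[rr, cc, drop = FALSE] %% (2 * pi)
  bin <- floor(ang / (2 * pi) * 36) %% 36 + 1
  h <- numeric(36)
  acc <- tapply(as.vector(w), as.vector(bin), sum)
  h[as.integer(names(acc))] <- acc
  for (i in 1:3)  # circular smoothing
    h <- (h + h[c(36, 1:35)] + h[c(2:36, 1)]) / 3
  p <- which.max(h)
  hl <- h[if (p == 1) 36 else p - 1]
  hr <- h[if (p == 36) 1 else p + 1]
  den <- hl - 2 * h[p] + hr
  dp <- if (abs(den) > 1e-12) 0.5 * (hl - hr) / den else 0
  ((p - 1 + dp) / 36 * 2 * pi) %% (2 * pi)
}

# 4x4 spatial x 8 orientation gradient histogram, unit-normalized
sift_descriptor <- function(gmag, gdir, r0, c0, sigma_local, theta) {
  NBP <- 4L; NBO <- 8L
  sbp <- 3 * sigma_local
  rad <- as.integer(ceiling(sbp * (NBP + 1) / 2 * sqrt(2)))
  n1 <- nrow(gmag); n2 <- ncol(gmag)
  rr <- max(2L, as.integer(round(r0)) - rad):min(n1 - 1L, as.integer(round(r0)) + rad)
  cc <- max(2L, as.integer(round(c0)) - rad):min(n2 - 1L, as.integer(round(c0)) + rad)
  if (!length(rr) || !length(cc)) return(rep(0, 128))
  dr <- rep(rr - r0, times = length(cc))
  dc <- rep(cc - c0, each = length(rr))
  ct <- cos(theta); st <- sin(theta)
  nx <- (ct * dr + st * dc) / sbp
  ny <- (-st * dr + ct * dc) / sbp
  keep <- abs(nx) < NBP / 2 + 0.5 & abs(ny) < NBP / 2 + 0.5
  if (!any(keep)) return(rep(0, 128))
  nx <- nx[keep]; ny <- ny[keep]
  w <- as.vector(gmag[rr, cc])[keep] *
    exp(-(nx^2 + ny^2) / (2 * (NBP / 2)^2))
  ang <- (as.vector(gdir[rr, cc])[keep] - theta) %% (2 * pi)
  bo <- ang / (2 * pi) * NBO
  bx <- nx + NBP / 2 - 0.5
  by <- ny + NBP / 2 - 0.5
  fx <- floor(bx); fy <- floor(by); fo <- floor(bo)
  wx <- bx - fx; wy <- by - fy; wo <- bo - fo
  acc <- numeric(NBP * NBP * NBO)
  for (ix in 0:1) for (iy in 0:1) for (io in 0:1) {
    X <- fx + ix; Y <- fy + iy; O <- (fo + io) %% NBO
    ok <- X >= 0 & X < NBP & Y >= 0 & Y < NBP
    if (!any(ok)) next
    ww <- w[ok] *
      (if (ix == 0) 1 - wx[ok] else wx[ok]) *
      (if (iy == 0) 1 - wy[ok] else wy[ok]) *
      (if (io == 0) 1 - wo[ok] else wo[ok])
    idx <- (X[ok] * NBP + Y[ok]) * NBO + O[ok] + 1
    part <- tapply(ww, idx, sum)
    pi_ <- as.integer(names(part))
    acc[pi_] <- acc[pi_] + part
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-12) return(rep(0, 128))
  acc <- pmin(acc / nrm, 0.2)
  acc / sqrt(sum(acc^2))
}

#' Detect SIFT keypoints and descriptors in a 2D image
#'
#' Standard DoG SIFT: per-octave Gaussian scale space, strict 26-neighbor
#' extrema, quadratic sub-pixel refinement, contrast and edge-response
#' rejection, dominant-orientation assignment and the 128-dimensional
#' appearance descriptor (4 x 4 spatial bins x 8 orientation bins,
#' normalized to unit Euclidean length).
#'
#' @param img 2D numeric matrix.
#' @param params a [sift_params()] list.
#' @return list with `keypoints` (data frame: `row`, `col`, `sigma`,
#'   `orient`, `response`; coordinates 1-based, possibly fractional,
#'   in the input image's pixel frame) and `descriptors` (matrix with
#'   one 128-vector row per keypoint).
#' @export
sift_detect <- function(img, params = sift_params()) {
  empty <- list(keypoints = data.frame(row = numeric(0), col = numeric(0),
                                       sigma = numeric(0), orient = numeric(0),
                                       response = numeric(0)),
                descriptors = matrix(0, 0, 128))
  img <- as.matrix(img)
  if (min(dim(img)) < params$min_size) return(empty)
  if (diff(range(img)) < 1e-12) return(empty)
  ns <- params$n_scales
  sig_tot <- params$sigma0 * 2^((0:(ns + 2)) / ns)
  kps <- NULL; descs <- NULL
  base <- img
  for (oct in seq_len(params$n_octaves)) {
    scale_fac <- 2^(oct - 1)
    if (min(dim(base)) < params$min_size) break
    G <- array(0, c(dim(base), ns + 3))
    G[, , 1] <- gauss_blur(base, sqrt(max(sig_tot[1]^2 - 0.25, 0.01)))
    for (l in 2:(ns + 3))
      G[, , l] <- gauss_blur(G[, , l - 1],
                             sqrt(sig_tot[l]^2 - sig_tot[l - 1]^2))
    D <- G[, , -1, drop = FALSE] - G[, , -(ns + 3), drop = FALSE]
    cand <- detect_extrema(D, params$contrast_thresh)
    if (!is.null(cand) && nrow(cand)) {
      grads <- vector("list", ns + 3)
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1]; c <- cand[i, 2]; l <- cand[i, 3]
        if (edge_like(D, r, c, l, params$edge_thresh)) next
        ref <- refine_extremum(D, r, c, l)
        if (abs(ref$val) < params$contrast_thresh) next
        r0 <- r + ref$off[1]; c0 <- c + ref$off[2]
        lev <- l + ref$off[3]
        sigma_local <- params$sigma0 * 2^(lev / ns)  # DoG level l ~ G level l+...
        gl <- l + 1L                                  # Gaussian level nearest the DoG level
        if (is.null(grads[[gl]])) {
          Gm <- G[, , gl]
          gx <- (rbind(Gm[-1, , drop = FALSE], Gm[nrow(Gm), , drop = FALSE]) -
                 rbind(Gm[1, , drop = FALSE], Gm[-nrow(Gm), , drop = FALSE])) / 2
          gy <- (cbind(Gm[, -1, drop = FALSE], Gm[, ncol(Gm), drop = FALSE]) -
                 cbind(Gm[, 1, drop = FALSE], Gm[, -ncol(Gm), drop = FALSE])) / 2
          grads[[gl]] <- list(mag = sqrt(gx^2 + gy^2), dir = atan2(gy, gx))
        }
        gm <- grads[[gl]]
        theta <- assign_orientation(gm$mag, gm$dir, r0, c0, sigma_local)
        desc <- sift_descriptor(gm$mag, gm$dir, r0, c0, sigma_local, theta)
        kps <- rbind(kps, c((r0 - 1) * scale_fac + 1, (c0 - 1) * scale_fac + 1,
                            sigma_local * scale_fac, theta, ref$val))
        descs <- rbind(descs, desc)
      }
    }
    base <- G[seq(1, nrow(G), by = 2), seq(1, ncol(G), by = 2), ns + 1]
  }
  if (is.null(kps)) return(empty)
  kp <- as.data.frame(kps)
  names(kp) <- c("row", "col", "sigma", "orient", "response")
  rownames(descs) <- NULL
  list(keypoints = kp, descriptors = descs)
}
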