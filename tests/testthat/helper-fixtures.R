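# Shared fixtures, built in code at test time.

# 2D slice with a bright Gaussian blob on a flat background
render_blob_slice <- function(cx, cy, r, amp, n = 20, noise = 0, bg = 0.5) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  img <- bg + amp * exp(-d2 / (2 * r^2))
  if (noise > 0) img <- img + matrix(stats::rnorm(n * n, 0, noise), n, n)
  img
}

make_feature <- function(x = c(0, 0, 0), sigma = 1, orient = 0,
                         appearance = rep(0, 128)) {
  list(x = x, sigma = sigma, orient = orient, appearance = appearance)
}

# random feature bank confined to one cube/orientation group
random_bank <- function(n, seed = 1, group_mix = TRUE, spread = 3) {
  set.seed(seed)
  desc <- matrix(stats::rnorm(n * 128), n, 128)
  desc <- desc / sqrt(rowSums(desc^2))
  sid <- sample(1:6, n, replace = TRUE)
  meta <- data.frame(
    subject_id = sprintf("S%02d", sid),
    group = if (group_mix) ifelse(sid %% 2 == 0, "HI", "NH")
            else rep("HI", n),
    cube_id = "c1.1.1", orientation = "axial",
    x = stats::runif(n, 0, spread), y = stats::runif(n, 0, spread),
    z = stats::runif(n, 0, spread),
    sigma = stats::runif(n, 0.8, 4), orient = stats::runif(n, 0, 2 * pi))
  structure(list(meta = meta, desc = desc), class = "sift_bank")
}

# brute-force similar-set oracle: literal loop over the four metrics
oracle_similar <- function(fi, bank, thr) {
  hits <- integer(0)
  for (j in seq_len(nrow(bank$meta))) {
    fj <- list(x = c(bank$meta$x[j], bank$meta$y[j], bank$meta$z[j]),
               sigma = bank$meta$sigma[j], orient = bank$meta$orient[j],
               appearance = bank$desc[j, ])
    if (delta_x(fi, fj) < thr$eps_x && delta_sigma(fi, fj) < thr$eps_sigma &&
        delta_o(fi, fj) < thr$eps_o && delta_a(fi, fj) < thr$eps_a)
      hits <- c(hits, j)
  }
  hits
}

# ---- cached expensive cohort runs shared across test files ----
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# overwhelming planted signal: every arm should separate perfectly
strong_effect_loocv <- function() cached("strong", {
  # "overwhelming" = planted group difference at least 5x every nuisance
  # amplitude in the generator (nuisance activations, coarse noise,
  # own-source ROI selection inflation, shared structural blobs)
  coh <- simulate_cohort(n_hi = 3, n_nh = 3, blob_effect = 2.0,
                         activation_effect = 3.0, seed = 11)
  loocv(coh)
})

# moderate complementary signal: structural blobs only reach the sMRI
# arm, activation sites only the fMRI arm
complementary_loocv <- function() cached("complementary", {
  coh <- simulate_cohort(n_hi = 5, n_nh = 5, blob_effect = 0.5,
                         activation_effect = 0.45, seed = 42)
  loocv(coh)
})

# zero planted effect, 10 seeds: per-arm test AUCs
null_cohort_aucs <- function() cached("null", {
  t(vapply(1:10, function(s) {
    coh <- simulate_cohort(n_hi = 6, n_nh = 6, blob_effect = 0,
                           activation_effect = 0, seed = 2000 + s)
    cv <- loocv(coh)
    stats::setNames(cv$summary$auc, rownames(cv$summary))
  }, numeric(3)))
})
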