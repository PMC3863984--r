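test_that("extreme-voxel selection takes the top fraction per sign class", {
  set.seed(8)
  map <- array(0, c(10, 4, 1))
  map[1:40] <- runif(40, 0.1, 1)          # 40 positive voxels
  sel <- select_extreme_voxels(map, 0.05)
  expect_equal(sum(sel$sign == 1), 2)     # ceiling(0.05 * 40)
  expect_equal(sort(map[sel$voxel[sel$sign == 1]], decreasing = TRUE),
               sort(as.vector(map), decreasing = TRUE)[1:2])
  # negation flips signs but not the selected set
  neg <- select_extreme_voxels(-map, 0.05)
  expect_setequal(neg$voxel, sel$voxel)
  expect_equal(sum(neg$sign == -1), 2)
  # all-zero map -> empty selection
  expect_equal(nrow(select_extreme_voxels(array(0, c(5, 5, 5)))), 0)
})

test_that("positive selection equals a brute-force sort-and-take oracle", {
  set.seed(9)
  map <- array(rnorm(1000), c(10, 10, 10))
  sel <- select_extreme_voxels(map, 0.05)
  pos <- which(as.vector(map) > 0)
  k <- ceiling(0.05 * length(pos))
  oracle <- pos[order(-as.vector(map)[pos], pos)][1:k]
  expect_equal(sort(sel$voxel[sel$sign == 1]), sort(oracle))
})

test_that("26-connectivity components respect corners and sign separation", {
  g <- c(10, 10, 10)
  lin <- function(i, j, k) (k - 1) * 100 + (j - 1) * 10 + i
  # two clusters separated by >= 2 voxels -> 2 ROIs
  sel <- data.frame(voxel = c(lin(2, 2, 2), lin(2, 2, 3), lin(8, 8, 8)),
                    sign = 1L)
  rois <- connected_rois(sel, g)
  expect_length(rois, 2)
  # diagonal corner touch merges under 26-connectivity
  sel <- data.frame(voxel = c(lin(2, 2, 2), lin(3, 3, 3)), sign = 1L)
  expect_length(connected_rois(sel, g), 1)
  # adjacent voxels of opposite sign never merge
  sel <- data.frame(voxel = c(lin(2, 2, 2), lin(3, 2, 2)), sign = c(1L, -1L))
  rois <- connected_rois(sel, g)
  expect_length(rois, 2)
  expect_setequal(vapply(rois, `[[`, integer(1), "sign"), c(1L, -1L))
})

test_that("dictionary order is deterministic and vectorization takes ROI means", {
  coh <- simulate_cohort(n_hi = 2, n_nh = 2, grid_shape = c(24, 24, 20),
                         seed = 6)
  d1 <- build_dictionary(coh)
  d2 <- build_dictionary(coh)
  expect_identical(lapply(d1$rois, `[[`, "voxels"),
                   lapply(d2$rois, `[[`, "voxels"))
  expect_equal(sum(d1$contrast_sizes), length(d1$rois))
  expect_equal(names(d1$contrast_sizes),
               c("speech_vs_silence", "speech_vs_tones", "tones_vs_silence"))
  # vectorizing the source subject reproduces the mean over its own ROI
  r1 <- d1$rois[[1]]
  src <- which(vapply(coh$subjects, `[[`, character(1), "subject_id") ==
               r1$subject)
  v <- vectorize_subject(coh$subjects[[src]], d1)
  expect_equal(v[1], mean(coh$subjects[[src]]$contrasts[[r1$contrast]][r1$voxels]))
  # a zeroed subject vectorizes to zeros
  zs <- coh$subjects[[1]]
  for (cn in names(zs$contrasts)) zs$contrasts[[cn]][] <- 0
  expect_true(all(vectorize_subject(zs, d1) == 0))
  # feature matrix covers dictionary + 3 sedation columns after assembly
  M <- feature_matrix(coh, d1)
  expect_equal(dim(M), c(4L, length(d1$rois)))
})

test_that("ROI merging collapses duplicates, keeps distant columns, and is idempotent", {
  set.seed(10)
  base <- matrix(rnorm(8 * 3, sd = 5), 8, 3)
  mat <- cbind(base[, 1], base[, 1], base[, 2], base[, 3], base[, 2])
  mg <- merge_rois(mat)
  expect_equal(ncol(mg$matrix), 3)
  expect_setequal(lapply(mg$membership, sort), list(c(1L, 2L), c(3L, 5L), 4L))
  expect_equal(mg$matrix[, 1], base[, 1])
  # mutually distant columns never merge
  far <- diag(6) * 100
  expect_equal(ncol(merge_rois(far)$matrix), 6)
  # idempotence
  mg2 <- merge_rois(mg$matrix)
  expect_equal(mg2$matrix, mg$matrix)
  expect_equal(lengths(mg2$membership), rep(1L, 3))
})

test_that("sedation one-hot encoding matches the identity rows", {
  expect_equal(unname(encode_sedation(2)), c(0, 1, 0))
  expect_equal(unname(encode_sedation(1)), c(1, 0, 0))
  expect_equal(rowSums(encode_sedation(c(1, 2, 3, 3))), rep(1, 4),
               ignore_attr = TRUE)
  expect_error(encode_sedation(4), "unknown")
})

test_that("the fMRI SVM separates a separable fixture with inclusive HI rule", {
  set.seed(12)
  n <- 12
  y <- rep(c(TRUE, FALSE), each = n / 2)
  mat <- cbind(ifelse(y, 1, -1) + rnorm(n, 0, 0.1),
               matrix(rnorm(n * 5), n))
  model <- train_fmri(mat, y)
  scores <- apply(mat, 1, score_row_fmri, model = model)
  expect_true(all(scores[y] >= 0) && all(scores[!y] < 0))
  expect_equal(ifelse(scores >= model$eps_f, "HI", "NH"),
               ifelse(y, "HI", "NH"))
  # the boundary itself is called HI (inclusive >=)
  expect_equal(ifelse(0 >= model$eps_f, "HI", "NH"), "HI")
  # flipping all labels flips every score
  flipped <- train_fmri(mat, !y)
  s2 <- apply(mat, 1, score_row_fmri, model = flipped)
  expect_lt(cor(scores, s2), -0.9)
})

test_that("feature importance accumulates |w| over selecting folds", {
  imp <- feature_importance(list(c(1, 2), c(1, 3), integer(0)),
                            list(c(0.5, -0.5), c(-0.25, 0.9), numeric(0)),
                            n_features = 4)
  expect_equal(imp, c(0.75, 0.5, 0.9, 0))
  # a planted strong feature dominates the ranking
  set.seed(13)
  y <- rep(c(TRUE, FALSE), each = 8)
  mat <- cbind(ifelse(y, 2, -2) + rnorm(16, 0, 0.2),
               matrix(rnorm(16 * 9), 16))
  sels <- list(); ws <- list()
  for (f in 1:4) {
    m <- train_fmri(mat[-f, ], y[-f])
    sels[[f]] <- m$selected; ws[[f]] <- m$w
  }
  imp <- feature_importance(sels, ws, ncol(mat))
  expect_equal(which.max(imp), 1L)
})

test_that("dictionaries round trip through NIfTI labels + JSON metadata", {
  coh <- simulate_cohort(n_hi = 1, n_nh = 1, grid_shape = c(24, 24, 20),
                         seed = 44)
  dict <- build_dictionary(coh)
  dir <- file.path(tempdir(), "dict-rt")
  jp <- write_dictionary(dict, dir)
  expect_equal(length(list.files(dir, pattern = "nii")), 3)
  back <- read_dictionary(jp)
  expect_equal(length(back$rois), length(dict$rois))
  expect_identical(lapply(back$rois, `[[`, "voxels"),
                   lapply(dict$rois, function(r) as.integer(r$voxels)))
  expect_equal(unname(back$contrast_sizes), unname(dict$contrast_sizes))
  # vectorization through the reloaded dictionary is identical
  expect_equal(vectorize_subject(coh$subjects[[1]], back),
               vectorize_subject(coh$subjects[[1]], dict))
  unlink(dir, recursive = TRUE)
})
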