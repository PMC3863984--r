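test_that("difference metrics match their closed forms", {
  fi <- make_feature(x = c(0, 0, 0), sigma = 5)
  fj <- make_feature(x = c(3, 4, 0), sigma = 5)
  expect_equal(delta_x(fi, fj), 1.0)          # 3-4-5 triangle / sigma 5
  oi <- make_feature(orient = 0.1)
  oj <- make_feature(orient = 2 * pi - 0.1)
  expect_equal(delta_o(oi, oj), 0.2)          # wrap-around
  f <- make_feature(x = c(1, 2, 3), sigma = 2, orient = 1,
                    appearance = runif(128))
  expect_equal(delta_x(f, f), 0)
  expect_equal(delta_sigma(f, f), 0)
  expect_equal(delta_o(f, f), 0)
  expect_equal(delta_a(f, f), 0)
  # scale-symmetric absolute log ratio
  a <- make_feature(sigma = 1); b <- make_feature(sigma = 2)
  expect_equal(delta_sigma(a, b), delta_sigma(b, a))
  expect_equal(delta_sigma(a, b), log(2))
  expect_error(delta_x(make_feature(sigma = 0), f), "positive")
})

test_that("similar_set uses strict inequalities and includes identical features", {
  thr <- similarity_thresholds()
  bank <- random_bank(5, seed = 2)
  fi <- as_f <- list(x = c(bank$meta$x[1], bank$meta$y[1], bank$meta$z[1]),
                     sigma = bank$meta$sigma[1], orient = bank$meta$orient[1],
                     appearance = bank$desc[1, ])
  expect_true(1 %in% similar_set(fi, bank, thr))

  # candidate exactly at the location threshold is excluded
  q <- make_feature(x = c(0, 0, 0), sigma = 1, orient = 0,
                    appearance = bank$desc[1, ])
  cand <- structure(list(
    meta = data.frame(subject_id = "S01", group = "HI", cube_id = "c",
                      orientation = "axial", x = 0.5, y = 0, z = 0,
                      sigma = 1, orient = 0),
    desc = matrix(bank$desc[1, ], 1)), class = "sift_bank")
  expect_length(similar_set(q, cand, thr), 0)  # delta_x == eps_x exactly
  cand$meta$x <- 0.49
  expect_length(similar_set(q, cand, thr), 1)
})

test_that("similar_set and the adjacency agree with the brute-force oracle", {
  thr <- similarity_thresholds(eps_x = 1.5, eps_sigma = 0.8, eps_o = pi / 2,
                               eps_a = 1.2)
  bank <- random_bank(50, seed = 7)
  adj <- hearclass:::similarity_adjacency(bank, thr)
  for (i in seq_len(50)) {
    fi <- list(x = c(bank$meta$x[i], bank$meta$y[i], bank$meta$z[i]),
               sigma = bank$meta$sigma[i], orient = bank$meta$orient[i],
               appearance = bank$desc[i, ])
    oracle <- oracle_similar(fi, bank, thr)
    expect_equal(sort(similar_set(fi, bank, thr)), oracle)
    expect_setequal(unname(which(adj[i, ])), setdiff(oracle, i))
  }
})

test_that("likelihood score follows the log frequency ratio with support rule", {
  # |S∩P| = 6, N_P = 3, |S∩C| = 2, N_C = 3, smoothing off -> ln 3
  expect_equal(likelihood_score(6, 2, 3, 3, support_min = 6, alpha = 0),
               log(3), tolerance = 1e-12)
  # support not met -> 0
  expect_equal(likelihood_score(2, 1, 3, 3, support_min = 6, alpha = 0), 0)
  # balanced frequencies -> 0
  expect_equal(likelihood_score(4, 4, 3, 3, support_min = 6, alpha = 1), 0)
  # smoothing handles empty intersections finitely
  expect_true(is.finite(likelihood_score(10, 0, 3, 3, support_min = 6)))
  # raw formula capped
  expect_equal(likelihood_score(10, 0, 3, 3, support_min = 6, alpha = 0), 50)
  expect_error(likelihood_score(1, 1, 0, 3), "required")
})

test_that("likelihood is antisymmetric under patient/healthy swap", {
  set.seed(5)
  for (rep in 1:20) {
    nsp <- sample(0:12, 1); nsc <- sample(0:12, 1)
    np <- sample(1:5, 1); nc <- sample(1:5, 1)
    sm <- sample(0:6, 1)
    l1 <- likelihood_score(nsp, nsc, np, nc, support_min = sm)
    l2 <- likelihood_score(nsc, nsp, nc, np, support_min = sm)
    expect_equal(l1, -l2, tolerance = 1e-12)
  }
})

test_that("feature labels follow the likelihood threshold", {
  expect_equal(label_feature(1.0, 0.9), 1L)
  expect_equal(label_feature(0.5, 0.9), 0L)
  expect_equal(label_feature(-1.0, 0.9), -1L)
  expect_equal(label_feature(c(0.9, -0.9), 0.9), c(0L, 0L))  # boundaries -> noise
})

test_that("feature evaluation never crosses cube or orientation groups", {
  bank <- random_bank(30, seed = 13)
  # duplicate the bank into a second cube with identical geometry; a
  # cross-group leak would double every similar-set count
  b2 <- bank
  b2$meta$cube_id <- "c2.1.1"
  both <- bind_banks(list(bank, b2))
  num <- as.integer(sub("S", "", both$meta$subject_id))
  both$meta$group <- ifelse(num %% 2 == 0, "HI", "NH")
  thr <- similarity_thresholds(eps_x = 2, eps_sigma = 1, eps_o = pi,
                               eps_a = 1.5)
  ev_single <- evaluate_features(
    structure(list(meta = both$meta[1:30, ], desc = both$desc[1:30, ]),
              class = "sift_bank"), thr, support_min = 1)
  ev_both <- evaluate_features(both, thr, support_min = 1)
  expect_equal(ev_both$meta$likelihood[1:30], ev_single$meta$likelihood)
})
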