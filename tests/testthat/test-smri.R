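make_labeled_bank <- function(n_per_class = 20, seed = 21) {
  # three linearly separable descriptor clusters, one per label class
  set.seed(seed)
  centers <- list(`-1` = c(rep(0.5, 40), rep(0, 88)),
                  `0`  = c(rep(0, 88), rep(0.5, 40)),
                  `1`  = c(rep(0, 44), rep(0.5, 40), rep(0, 44)))
  desc <- NULL; lab <- integer(0)
  for (k in names(centers)) {
    d <- matrix(rep(centers[[k]], n_per_class), n_per_class, byrow = TRUE) +
      matrix(rnorm(n_per_class * 128, 0, 0.05), n_per_class)
    desc <- rbind(desc, d)
    lab <- c(lab, rep(as.integer(k), n_per_class))
  }
  n <- nrow(desc)
  meta <- data.frame(subject_id = "S01", group = "HI", cube_id = "c1.1.1",
                     orientation = "axial",
                     x = runif(n, 0, 20), y = runif(n, 0, 20),
                     z = runif(n, 0, 20),
                     sigma = runif(n, 1, 3), orient = runif(n, 0, 2 * pi))
  list(bank = structure(list(meta = meta, desc = desc), class = "sift_bank"),
       labels = lab)
}

test_that("per-group feature classifiers recover separable label clusters", {
  fx <- make_labeled_bank()
  X <- sift_vectors(fx$bank)
  clf <- hearclass:::train_group_classifier(X, fx$labels)
  expect_equal(clf$type, "svm")
  pred <- hearclass:::predict_group_classifier(clf, X)
  expect_gte(mean(pred == fx$labels), 0.9)
})

test_that("degenerate label groups get constant predictors", {
  fx <- make_labeled_bank(n_per_class = 5)
  X <- sift_vectors(fx$bank)
  noise_only <- hearclass:::train_group_classifier(X[fx$labels == 0, ],
                                                   rep(0L, 5))
  expect_equal(noise_only$type, "constant")
  expect_equal(hearclass:::predict_group_classifier(noise_only, X[1:3, ]),
               rep(0L, 3))
})

test_that("Csum sums predicted labels and skips untrained groups", {
  model <- structure(list(
    classifiers = list("c1.1.1|axial" = list(type = "constant", value = 1L),
                       "c1.1.1|coronal" = list(type = "constant", value = -1L)),
    eps_s = 0), class = "smri_model")
  bank <- random_bank(10, seed = 3)
  bank$meta$orientation <- rep(c("axial", "coronal"), 5)
  # 5 features predicted +1, 5 predicted -1 -> Csum 0
  expect_equal(score_bank_smri(bank, model), 0)
  bank$meta$orientation[1:10] <- "axial"
  expect_equal(score_bank_smri(bank, model), 10)
  # untrained group contributes nothing
  bank$meta$cube_id <- "c9.9.9"
  expect_equal(score_bank_smri(bank, model), 0)
  # negating every prediction negates Csum
  model$classifiers[["c1.1.1|axial"]]$value <- -1L
  bank$meta$cube_id <- "c1.1.1"
  expect_equal(score_bank_smri(bank, model), -10)
})

test_that("the subject threshold balances training FPR and FNR", {
  # perfectly separated scores: any midpoint in the gap balances; the
  # smallest balancing threshold is chosen
  th <- hearclass:::balanced_threshold(c(-3, -2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(th, 0)
  expect_true(all(c(2, 3) > th) && all(c(-3, -2) <= th))
  # at eps_s = 0 a Csum of 0 is called NH (strict >)
  expect_equal(ifelse(0 > th, "HI", "NH"), "NH")
})

test_that("training the sMRI arm end-to-end labels groups and sets eps_s", {
  # two subjects per group, descriptor clusters tied to group identity
  set.seed(31)
  mk <- function(sid, grp, center) {
    n <- 12
    desc <- matrix(rep(center, n), n, byrow = TRUE) +
      matrix(rnorm(n * 128, 0, 0.03), n)
    desc <- desc / sqrt(rowSums(desc^2))
    meta <- data.frame(subject_id = sid, group = grp, cube_id = "c1.1.1",
                       orientation = "axial",
                       x = rnorm(n, 10, 0.3), y = rnorm(n, 10, 0.3),
                       z = rnorm(n, 10, 0.3),
                       sigma = 2, orient = runif(n, 0, 0.5))
    structure(list(meta = meta, desc = desc), class = "sift_bank")
  }
  chi <- c(rep(1, 64), rep(0, 64)); cnh <- c(rep(0, 64), rep(1, 64))
  bank <- bind_banks(list(mk("P1", "HI", chi), mk("P2", "HI", chi),
                          mk("C1", "NH", cnh), mk("C2", "NH", cnh)))
  model <- train_smri(bank, support_min = 4)
  expect_s3_class(model, "smri_model")
  sc <- model$train_scores
  expect_true(all(sc$csum[sc$group == "HI"] > model$eps_s))
  expect_true(all(sc$csum[sc$group == "NH"] <= model$eps_s))
})

test_that("the structural arm recovers planted blob signal and stays at chance under the null", {
  strong <- strong_effect_loocv()
  expect_gte(strong$summary["sMRI", "auc"], 0.8)
  nulls <- null_cohort_aucs()
  m <- mean(nulls[, "sMRI"])
  se <- sd(nulls[, "sMRI"]) / sqrt(nrow(nulls))
  expect_lt(abs(m - 0.5), 3 * se)
})
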