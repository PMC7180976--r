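test_that("PCA ratios match the correlation-matrix eigenvalue oracle", {
  set.seed(1)
  n <- 150
  X <- matrix(stats::rnorm(n * 4), n, 4)
  X[, 2] <- X[, 1] * 2 + stats::rnorm(n, 0, 0.1)
  d <- tibble::as_tibble(as.data.frame(X))
  ps <- pca_summary(d)
  ev <- eigen(stats::cor(X), symmetric = TRUE)$values
  expect_equal(ps$explained$ratio, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(ps$explained$ratio) <= 1e-12))
  expect_equal(sum(ps$explained$ratio), 1, tolerance = 1e-12)
  # collinear 2-D data: first component explains everything
  d2 <- tibble::tibble(a = 1:50, b = 2 * (1:50) + 3)
  expect_equal(pca_summary(d2)$explained$ratio[1], 1, tolerance = 1e-12)
  # isotropic Gaussian: ratios near (0.5, 0.5)
  d3 <- tibble::as_tibble(as.data.frame(matrix(stats::rnorm(4000), ncol = 2)))
  expect_equal(pca_summary(d3)$explained$ratio, c(0.5, 0.5), tolerance = 0.05)
  d4 <- d2; d4$c <- 1
  expect_warning(pca_summary(d4), "zero-variance")
})

test_that("NCA puts its weight on the informative feature", {
  set.seed(2)
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(stats::rnorm(n * 10), n, 10)
  X[, 1] <- X[, 1] + ifelse(y == "a", -2, 2)
  d <- tibble::as_tibble(as.data.frame(X)); d$label <- y
  w <- nca_feature_weights(d, seed = 1)
  expect_true(all(w$weight >= 0))
  expect_equal(which.max(w$weight), 1L)
  expect_true(w$selected[1])
  expect_lt(stats::median(w$weight[-1]), 0.1)
  expect_error(nca_feature_weights(d[d$label == "a", ]), "2 classes")
})

test_that("duplicated informative features share their NCA weight", {
  set.seed(3)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  x1 <- stats::rnorm(n) + ifelse(y == "a", -1.5, 1.5)
  d <- tibble::tibble(f1 = x1, f2 = x1 + stats::rnorm(n, 0, 1e-3),
                      f3 = stats::rnorm(n), label = y)
  w <- nca_feature_weights(d, seed = 1)
  expect_lt(max(w$weight[1:2]) / max(min(w$weight[1:2]), 1e-9), 2)
})

test_that("participant-level splits keep groups exclusive and reproducible", {
  d <- gaussian_dataset(n = 160, seed = 4)
  sp <- split_dataset(d, seed = 9)
  expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test), nrow(d))
  train_groups <- unique(c(sp$train$group, sp$validation$group))
  expect_length(intersect(train_groups, unique(sp$test$group)), 0)
  # 8 groups at 0.75 -> 6 train, 2 test participants
  expect_length(unique(sp$test$group), 2)
  expect_length(train_groups, 6)
  sp2 <- split_dataset(d, seed = 9)
  expect_identical(sp, sp2)
  d1 <- d; d1$group[d1$label == "a"] <- "only_one"
  expect_error(split_dataset(d1), "group_level = FALSE")
})

test_that("all four classifiers separate well-separated Gaussians perfectly", {
  d <- gaussian_dataset(n = 160, sep = 6, seed = 5)
  sp <- split_dataset(d, seed = 2)
  reps <- train_and_evaluate(sp, seed = 2)
  for (alg in c("svm", "logistic", "tree", "xgboost")) {
    expect_equal(reps[[alg]]$accuracy, 1.0)
    expect_equal(reps[[alg]]$auc, 1.0)
    # chosen hyperparameters come from the declared grid
    g <- default_grids()[[alg]]
    for (p in names(reps[[alg]]$params))
      expect_true(reps[[alg]]$params[[p]] %in% g[[p]])
  }
  gl <- glance(reps$svm)
  expect_equal(gl$accuracy, 1.0)
  expect_equal(nrow(tidy(reps$xgboost)), 3)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(6)
  d <- gaussian_dataset(n = 200, sep = 6, seed = 6)
  d$label <- sample(d$label)
  sp <- split_dataset(d, group_level = FALSE, seed = 3)
  r <- train_and_evaluate(sp, algorithms = "svm",
                          grids = list(svm = expand.grid(cost = 10, gamma = 0.01)),
                          seed = 3)$svm
  expect_gt(r$auc, 0.35)
  expect_lt(r$auc, 0.65)
})

test_that("home-grown ROC/AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    scores <- stats::rnorm(60)
    truth <- stats::runif(60) < 0.4 + 0.2 * (scores > 0)
    rc <- roc_curve(scores, truth)
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
    expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-10)
  }
  # AUC invariant under strictly monotone score transforms
  scores <- stats::rnorm(100); truth <- stats::runif(100) < 0.5
  expect_equal(roc_curve(exp(scores), truth)$auc, roc_curve(scores, truth)$auc)
  expect_true(is.na(roc_curve(scores, rep(TRUE, 100))$auc))
})

test_that("feature selection restricts the trained model to surviving columns", {
  set.seed(8)
  d <- gaussian_dataset(n = 160, sep = 6, seed = 8)
  w <- nca_feature_weights(d, seed = 1)
  sp <- split_dataset(d, seed = 4)
  r <- train_and_evaluate(sp, algorithms = "logistic",
                          selection = w, seed = 4)$logistic
  expect_identical(r$selected_features, w$feature[w$selected])
  expect_identical(r$feature_cols, w$feature[w$selected])
})

test_that("predict_phases scores new records and checks columns", {
  d <- gaussian_dataset(n = 120, sep = 6, seed = 9)
  sp <- split_dataset(d, seed = 5)
  r <- train_and_evaluate(sp, algorithms = "svm",
                          grids = list(svm = expand.grid(cost = 10, gamma = 0.01)),
                          seed = 5)$svm
  pred <- predict_phases(r, d)
  expect_length(pred, nrow(d))
  expect_gt(mean(pred == d$label), 0.98)
  expect_error(predict_phases(r, d[, 1:2]), "missing feature")
})

test_that("simulated cohorts separate by proficiency but not under identical profiles", {
  co <- make_cohort(coach_profile(duration = 25), novice_profile(duration = 25),
                    n_trials = 6, n_participants = 4, seed = 11)
  sp <- split_dataset(co$features, seed = 11)
  r <- train_and_evaluate(sp, algorithms = "svm",
                          grids = list(svm = expand.grid(cost = 10, gamma = 0.01)),
                          seed = 11)$svm
  expect_gt(r$auc, 0.9)

  co0 <- make_cohort(coach_profile(duration = 25), coach_profile(duration = 25),
                     n_trials = 6, n_participants = 4, seed = 12)
  sp0 <- split_dataset(co0$features, seed = 12)
  r0 <- train_and_evaluate(sp0, algorithms = "svm",
                           grids = list(svm = expand.grid(cost = 10, gamma = 0.01)),
                           seed = 12)$svm
  expect_gt(r0$auc, 0.35); expect_lt(r0$auc, 0.65)
})
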