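make_blobs <- function(n_per_class, d = 5, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
    colnames(x) <- paste0("f", seq_len(d))
    list(features = x, labels = rep(c(0L, 1L), each = n_per_class))
  })
}

test_that("all four classifiers separate well-separated Gaussian blobs", {
  ds <- make_blobs(30)
  cv <- cv_protocol(n_folds = 5, n_iterations = 1, seed = 3)
  for (clf in c("rf", "knn", "svm", "lda")) {
    r <- run_baseline(ds, baseline_spec(clf, "fluency", cv = cv))
    expect_gte(r$summary$mean[r$summary$metric == "accuracy"], 0.99)
  }
})

test_that("permuted labels drive accuracy to chance", {
  ds <- make_blobs(100, sep = 10, seed = 5)
  ds$labels <- withr::with_seed(11, sample(ds$labels))
  r <- run_baseline(ds, baseline_spec("lda", "fluency",
                                      cv = cv_protocol(n_folds = 5,
                                                       n_iterations = 2,
                                                       seed = 6)))
  acc <- r$summary$mean[r$summary$metric == "accuracy"]
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("baseline runs are bit-reproducible under a fixed seed", {
  ds <- make_blobs(20, sep = 3, seed = 7)
  spec <- baseline_spec("rf", "fluency",
                        cv = cv_protocol(n_folds = 4, n_iterations = 2,
                                         seed = 9))
  r1 <- run_baseline(ds, spec)
  r2 <- run_baseline(ds, spec)
  expect_identical(r1$per_iteration, r2$per_iteration)
})

test_that("zero-variance feature columns are dropped with a warning", {
  ds <- make_blobs(15, d = 3, seed = 8)
  ds$features <- cbind(ds$features, dead = 1)
  w <- testthat::capture_warnings(
    run_baseline(ds, baseline_spec("lda", "fluency",
                                   cv = cv_protocol(n_folds = 3,
                                                    n_iterations = 1,
                                                    seed = 2))))
  expect_true(any(grepl("zero-variance", w)))
})

test_that("standardization statistics come from the training rows only", {
  ds <- make_blobs(20, d = 4, sep = 2, seed = 10)
  tr <- 1:30
  te <- 31:40
  scores <- schnetr:::fit_predict_classifier(
    "lda", ds$features[tr, ], ds$labels[tr], ds$features[te, ],
    list(), seed = 1)
  # reference: explicit train-fold scaler, then LDA on the scaled spaces
  mu <- colMeans(ds$features[tr, ])
  sdv <- apply(ds$features[tr, ], 2, sd)
  ztr <- scale(ds$features[tr, ], mu, sdv)
  zte <- scale(ds$features[te, ], mu, sdv)
  fit <- MASS::lda(ztr, grouping = factor(ds$labels[tr], levels = c(0, 1)))
  ref <- stats::predict(fit, zte)$posterior[, "1"]
  expect_equal(unname(scores), unname(ref), tolerance = 1e-12)
  # corrupting the test rows cannot change a train-only scaler's statistics:
  # predictions for untouched rows stay identical
  xte2 <- ds$features[te, ]
  xte2[1, ] <- xte2[1, ] + 1000
  scores2 <- schnetr:::fit_predict_classifier(
    "lda", ds$features[tr, ], ds$labels[tr], xte2, list(), seed = 1)
  expect_equal(scores2[-1], scores[-1], tolerance = 1e-12)
})

test_that("the benchmark grid covers every cell with four metrics", {
  ds <- make_blobs(15, seed = 12)
  feats <- list(fluency = ds$features, lp = ds$features + 0.1)
  grid <- benchmark_grid(list(features = feats, labels = ds$labels),
                         feature_sets = c("fluency", "lp"),
                         classifiers = c("rf", "svm"),
                         cv = cv_protocol(n_folds = 3, n_iterations = 1,
                                          seed = 4))
  expect_equal(nrow(grid), 4L)
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in%
                    names(grid)))
  empty <- benchmark_grid(list(features = feats, labels = ds$labels),
                          feature_sets = character(0),
                          cv = cv_protocol(n_folds = 3, n_iterations = 1))
  expect_equal(nrow(empty), 0L)
})
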