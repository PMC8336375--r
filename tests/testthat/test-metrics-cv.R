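test_that("metrics from fixed confusion counts match hand arithmetic", {
  m <- metrics_from_counts(list(tp = 9, fn = 1, fp = 2, tn = 8))
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["precision"]), 9 / 11, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.9)
  expect_equal(unname(m["f1"]), 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9),
               tolerance = 1e-12)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
})

test_that("perfect scores yield all seven metrics at 1 and ties give AUC 0.5", {
  labels <- rep(c(1, 0), each = 10)
  perfect <- compute_metrics(c(rep(1, 10), rep(0, 10)), labels)$metrics
  expect_true(all(abs(perfect - 1) < 1e-12))
  tied <- compute_metrics(rep(0.4, 20), labels)$metrics
  expect_equal(unname(tied["auc"]), 0.5)
})

test_that("AUC is a rank statistic: tie credit, monotone invariance, oracle match", {
  set.seed(19)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- round(runif(60), 1)  # force ties
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(plogis(5 * scores - 2), labels), a)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("degenerate inputs follow the documented conventions", {
  out <- suppressWarnings(compute_metrics(c(0.1, 0.2), c(0, 0)))
  expect_true(is.na(out$metrics["auc"]))
  expect_warning(compute_metrics(c(0.1, 0.2), c(0, 0)), "AUC undefined")
  expect_equal(unname(out$metrics["precision"]), 0)  # no positive predictions
  expect_error(auc_rank(c(0.5, 0.6), c(1, 1)), "one class")
})

test_that("accuracy and F1 identities hold on random confusion counts", {
  set.seed(33)
  for (i in 1:25) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("tp", "fn", "fp", "tn")))
    if (cc$tp + cc$fn + cc$fp + cc$tn == 0) next
    m <- metrics_from_counts(cc)
    expect_equal(unname(m["accuracy"]),
                 (cc$tp + cc$tn) / (cc$tp + cc$fn + cc$fp + cc$tn))
    if (m["precision"] + m["recall"] > 0) {
      expect_equal(unname(m["f1"]),
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    }
    expect_equal(unname(m["recall"]), unname(m["sensitivity"]))
  }
})

test_that("confidence intervals follow the normal approximation exactly", {
  acc <- rep(c(0.9, 1.0), 15)
  rep_df <- data.frame(iteration = 1:30, accuracy = acc)
  r <- cv_report(rep_df)
  expect_equal(r$summary$mean, 0.95)
  half <- 1.96 * stats::sd(acc) / sqrt(30)
  expect_equal(r$summary$ci_hi - r$summary$mean, half)
  expect_equal(half, 0.0182, tolerance = 0.005)
  # constant metric collapses to a zero-width interval
  rz <- cv_report(data.frame(iteration = 1:30, accuracy = rep(0.8, 30)))
  expect_equal(rz$summary$ci_lo, rz$summary$ci_hi)
  expect_equal(rz$summary$mean, 0.8)
})

test_that("stratified folds partition every sample exactly once", {
  labels <- rep(c(0, 1), c(35, 25))
  cv <- cv_protocol(n_folds = 10, n_iterations = 3, seed = 4)
  for (it in 1:3) {
    folds <- make_folds(labels, cv, it)
    expect_equal(sort(unique(folds)), 1:10)
    expect_equal(length(folds), 60L)
    # stratification: class balance per fold within one sample
    for (k in 1:10) {
      expect_lte(abs(sum(labels[folds == k]) - 2.5), 1.5)
    }
  }
  expect_false(identical(make_folds(labels, cv, 1), make_folds(labels, cv, 2)))
})

test_that("subject-disjoint folds never split a subject and demand subject ids", {
  labels <- rep(c(0, 1), each = 20)
  subjects <- rep(sprintf("s%02d", 1:10), each = 4)
  cv <- cv_protocol(n_folds = 5, n_iterations = 2, subject_disjoint = TRUE,
                    seed = 7)
  folds <- make_folds(labels, cv, 1, subjects)
  for (s in unique(subjects)) {
    expect_equal(length(unique(folds[subjects == s])), 1L)
  }
  expect_error(make_folds(labels, cv, 1, subjects = NULL),
               "subject identifiers")
})

test_that("a constant classifier on balanced data scores chance accuracy", {
  ds <- list(labels = rep(c(0L, 1L), 20))
  fp <- function(dataset, tr, te, seed) rep(0, length(te))
  r <- suppressWarnings(
    cross_validate(ds, fp, cv_protocol(n_folds = 5, n_iterations = 3,
                                       seed = 2)))
  expect_equal(r$summary$mean[r$summary$metric == "accuracy"], 0.5)
  expect_equal(r$summary$ci_lo[r$summary$metric == "accuracy"],
               r$summary$ci_hi[r$summary$metric == "accuracy"])
  # every iteration tested every sample exactly once (pooled OOF scores)
  expect_equal(nrow(r$per_iteration), 3L)
})

test_that("CV reports export per-iteration CSV and JSON summaries", {
  rep_df <- data.frame(iteration = 1:5, accuracy = seq(0.8, 1.0, 0.05))
  r <- cv_report(rep_df)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_cv_report(r, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 5L)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$mean, 0.9)
})
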