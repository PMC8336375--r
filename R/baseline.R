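#' Baseline classifier specification
#'
#' One cell of the feature-engineering benchmark: a feature set paired
#' with one of four classic classifiers. Hyperparameter defaults: random
#' forest with 500 trees; KNN with k = 5 (Euclidean); SVM with an RBF
#' kernel, C = 1, gamma = 1/d; LDA without shrinkage.
#'
#' @param classifier One of `"rf"`, `"knn"`, `"svm"`, `"lda"`.
#' @param feature_set One of [feature_set_names()].
#' @param hyper Named list overriding defaults (`ntree`, `k`, `cost`,
#'   `gamma`).
#' @param cv A [cv_protocol()].
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(classifier, feature_set, hyper = list(),
                          cv = cv_protocol()) {
  classifier <- match.arg(classifier, c("rf", "knn", "svm", "lda"))
  if (!feature_set %in% feature_set_names()) {
    stop("unknown feature set '", feature_set, "'; valid sets: ",
         paste(feature_set_names(), collapse = ", "))
  }
  structure(list(classifier = classifier, feature_set = feature_set,
                 hyper = hyper, cv = cv),
            class = "baseline_spec")
}

# Fit one classifier on standardized training features and return class-1
# scores for the test rows. Standardization statistics come from the
# training rows only; zero-variance training columns are dropped.
fit_predict_classifier <- function(classifier, x_tr, y_tr, x_te, hyper,
                                   seed) {
  mu <- colMeans(x_tr)
  sdv <- apply(x_tr, 2L, stats::sd)
  keep <- sdv > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature column(s) dropped")
  }
  if (!any(keep)) return(rep(0.5, nrow(x_te)))
  zs <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep]),
                          2L, sdv[keep], `/`)
  x_tr <- zs(x_tr); x_te <- zs(x_te)
  y_f <- factor(y_tr, levels = c(0L, 1L))
  with_seed(seed, switch(classifier,
    rf = {
      fit <- randomForest::randomForest(
        x_tr, y_f, ntree = hyper$ntree %||% 500L)
      stats::predict(fit, x_te, type = "prob")[, "1"]
    },
    knn = {
      pr <- class::knn(x_tr, x_te, y_f, k = hyper$k %||% 5L, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    svm = {
      fit <- e1071::svm(x_tr, y_f, kernel = "radial",
                        cost = hyper$cost %||% 1,
                        gamma = hyper$gamma %||% (1 / ncol(x_tr)),
                        probability = TRUE)
      attr(stats::predict(fit, x_te, probability = TRUE),
           "probabilities")[, "1"]
    },
    lda = {
      fit <- MASS::lda(x_tr, grouping = y_f)
      stats::predict(fit, x_te)$posterior[, "1"]
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one baseline cell under the CV protocol
#'
#' @param dataset A list with `features` (matrix or named list of matrices
#'   keyed by feature set), `labels`, and optionally `subjects`.
#' @param spec A [baseline_spec()].
#' @param verbose Print per-iteration progress.
#' @return A `cv_report` for the cell.
#' @export
run_baseline <- function(dataset, spec, verbose = FALSE) {
  feats <- if (is.list(dataset$features) && !is.data.frame(dataset$features)) {
    dataset$features[[spec$feature_set]]
  } else dataset$features
  if (is.null(feats)) {
    stop("dataset carries no features for set '", spec$feature_set, "'")
  }
  stopifnot(nrow(feats) == length(dataset$labels))
  ds <- list(features = feats, labels = as.integer(dataset$labels),
             subjects = dataset$subjects)
  fp <- function(d, tr, te, seed) {
    fit_predict_classifier(spec$classifier, d$features[tr, , drop = FALSE],
                           d$labels[tr], d$features[te, , drop = FALSE],
                           spec$hyper, seed)
  }
  cross_validate(ds, fp, spec$cv, verbose = verbose)
}

#' Full classifier-by-feature-set benchmark grid
#'
#' Runs every classifier on every feature set under one shared CV protocol
#' and tabulates accuracy, precision, recall and F1 (positive class).
#'
#' @param dataset As in [run_baseline()]; `features` must be a named list
#'   of matrices covering `feature_sets`.
#' @param feature_sets Character vector of feature-set names.
#' @param classifiers Character vector among rf/knn/svm/lda.
#' @param cv A [cv_protocol()] shared by every cell.
#' @param verbose Print progress.
#' @return Data frame with one row per (classifier, feature_set) cell and
#'   metric columns; attribute `"reports"` holds the full `cv_report`s.
#' @export
benchmark_grid <- function(dataset, feature_sets,
                           classifiers = c("rf", "knn", "svm", "lda"),
                           cv = cv_protocol(), verbose = FALSE) {
  cells <- expand.grid(classifier = classifiers, feature_set = feature_sets,
                       stringsAsFactors = FALSE)
  reports <- list()
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- baseline_spec(cells$classifier[i], cells$feature_set[i], cv = cv)
    if (verbose) message("cell ", sp$classifier, " x ", sp$feature_set)
    rep <- run_baseline(dataset, sp)
    reports[[paste(sp$classifier, sp$feature_set, sep = "_")]] <<- rep
    s <- rep$summary
    data.frame(classifier = sp$classifier, feature_set = sp$feature_set,
               accuracy = s$mean[s$metric == "accuracy"],
               precision = s$mean[s$metric == "precision"],
               recall = s$mean[s$metric == "recall"],
               f1 = s$mean[s$metric == "f1"])
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(classifier = character(0), feature_set = character(0),
               accuracy = numeric(0), precision = numeric(0),
               recall = numeric(0), f1 = numeric(0))
  }
  attr(out, "reports") <- reports
  out
}
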