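#' Cross-validation protocol
#'
#' Repeated stratified k-fold cross-validation: 30 independent iterations
#' of ten-fold CV by default, each iteration re-partitioning the data with
#' its own derived seed. With `subject_disjoint = TRUE` folds are assigned
#' at the subject level so clips from one speaker never span the
#' train/test boundary.
#'
#' @param n_folds Number of folds (>= 2).
#' @param n_iterations Number of independent repetitions.
#' @param stratified Preserve class balance across folds.
#' @param subject_disjoint Assign folds by subject identifier.
#' @param seed Base seed; iteration `i` uses a seed derived from it.
#' @return A `cv_protocol` list.
#' @export
cv_protocol <- function(n_folds = 10L, n_iterations = 30L, stratified = TRUE,
                        subject_disjoint = FALSE, seed = 1L) {
  stopifnot(n_folds >= 2L, n_iterations >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 stratified = stratified, subject_disjoint = subject_disjoint,
                 seed = as.integer(seed)),
            class = "cv_protocol")
}

#' Fold assignment for one CV iteration
#'
#' @param labels 0/1 labels.
#' @param cv A [cv_protocol()].
#' @param iteration Iteration number (selects the derived seed).
#' @param subjects Optional subject identifiers, required when
#'   `cv$subject_disjoint` is set.
#' @return Integer fold id (1..n_folds) per sample.
#' @export
make_folds <- function(labels, cv, iteration = 1L, subjects = NULL) {
  n <- length(labels)
  if (cv$subject_disjoint) {
    if (is.null(subjects)) {
      stop("configuration error: subject_disjoint CV requested but the ",
           "dataset carries no subject identifiers")
    }
    su <- unique(subjects)
    sl <- vapply(su, function(s) round(mean(labels[subjects == s])), numeric(1))
    sf <- assign_folds(sl, cv, iteration)
    sf[match(subjects, su)]
  } else {
    assign_folds(labels, cv, iteration)
  }
}

assign_folds <- function(labels, cv, iteration) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(derive_seed(cv$seed, iteration), {
    if (cv$stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(cv$n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(cv$n_folds), n)
    }
  })
  folds
}

#' Repeated k-fold cross-validation with pooled out-of-fold metrics
#'
#' For each iteration an independent stratified partition is drawn; the
#' supplied `fit_predict` closure is trained on each training fold and
#' scored on the held-out fold; the out-of-fold scores are pooled and the
#' seven metrics computed once per iteration. The 95% confidence interval
#' is the normal approximation `mean +/- 1.96 sd / sqrt(n_iterations)`.
#'
#' @param dataset A list with at least `labels` (0/1); extra fields (e.g.
#'   `images`, `features`, `subjects`) are passed through to `fit_predict`.
#' @param fit_predict Function `(dataset, train_idx, test_idx, seed)`
#'   returning class-1 scores for `test_idx`.
#' @param cv A [cv_protocol()].
#' @param verbose Print per-iteration accuracy.
#' @return A `cv_report`: `per_iteration` data frame (one row per
#'   iteration, seven metric columns) and `summary` data frame with
#'   `mean`, `ci_lo`, `ci_hi` per metric.
#' @export
cross_validate <- function(dataset, fit_predict, cv = cv_protocol(),
                           verbose = FALSE) {
  labels <- as.integer(dataset$labels)
  n <- length(labels)
  stopifnot(n >= cv$n_folds)
  metric_names <- c("accuracy", "precision", "recall", "f1", "sensitivity",
                    "specificity", "auc")
  rows <- matrix(NA_real_, cv$n_iterations, length(metric_names),
                 dimnames = list(NULL, metric_names))
  for (it in seq_len(cv$n_iterations)) {
    folds <- make_folds(labels, cv, it, dataset$subjects)
    scores <- rep(NA_real_, n)
    for (k in seq_len(cv$n_folds)) {
      te <- which(folds == k)
      if (length(te) == 0L) next
      tr <- which(folds != k)
      scores[te] <- fit_predict(dataset, tr, te,
                                seed = derive_seed(cv$seed, it * 1000 + k))
    }
    stopifnot(!anyNA(scores)) # every sample tested exactly once
    rows[it, ] <- compute_metrics(scores, labels)$metrics
    if (verbose) {
      message(sprintf("iteration %2d  accuracy %.4f", it, rows[it, 1L]))
    }
  }
  per_iteration <- data.frame(iteration = seq_len(cv$n_iterations), rows)
  cv_report(per_iteration)
}

#' Build a CV report (per-iteration metrics plus 95% CIs)
#'
#' @param per_iteration Data frame with an `iteration` column and one
#'   column per metric.
#' @return A `cv_report` object.
#' @export
cv_report <- function(per_iteration) {
  mn <- setdiff(names(per_iteration), "iteration")
  n_it <- nrow(per_iteration)
  summ <- do.call(rbind, lapply(mn, function(m) {
    v <- per_iteration[[m]]
    mu <- mean(v)
    half <- if (n_it > 1L) 1.96 * stats::sd(v) / sqrt(n_it) else 0
    data.frame(metric = m, mean = mu, ci_lo = mu - half, ci_hi = mu + half)
  }))
  structure(list(per_iteration = per_iteration, summary = summ,
                 n_iterations = n_it),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d iterations>\n", x$n_iterations))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a CV report as CSV (per-iteration rows) and JSON (summary)
#'
#' @param report A `cv_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
export_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_iteration, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Closure training a Sch-net on a fold and scoring the held-out clips
#'
#' @param config A [schnet_config()].
#' @param tc A [train_config()]; its seed is replaced by the fold seed.
#' @param augment_policy Optional training-time [augmentation_policy()]
#'   (never applied to test folds).
#' @return A `fit_predict` function for [cross_validate()].
#' @export
schnet_fit_predict <- function(config, tc = train_config(),
                               augment_policy = NULL) {
  function(dataset, train_idx, test_idx, seed) {
    tc$seed <- as.integer(seed %% 2147483647)
    cfg <- config
    cfg$seed <- tc$seed
    model <- build_schnet(cfg)
    fit <- train_schnet(model, dataset$images[train_idx],
                        dataset$labels[train_idx], tc,
                        augment_policy = augment_policy)
    predict_schnet(fit$model, dataset$images[test_idx])[, 2L]
  }
}
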