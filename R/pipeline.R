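#' The 60:20:20 training protocol
#'
#' Labeled variants are partitioned 60:20:20 into train / validation / test.
#' Hyperparameters are tuned on the training partition by cross-validated
#' random search; candidate (algorithm, feature set) models are compared on
#' the validation partition over repeated tuned runs; the selected model is
#' refit on train + validation (80%) and evaluated exactly once on the
#' untouched test partition.
#'
#' @name training_protocol
NULL

#' Split specification
#'
#' @param train,validation,test Fractions summing to 1 (default 0.6/0.2/0.2).
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify the partition by label (default TRUE; keeps
#'   the smaller deleterious class balanced across partitions).
#' @return List of class `split_spec`.
#' @export
split_spec <- function(train = 0.6, validation = 0.2, test = 0.2,
                       seed = 1L, stratified = TRUE) {
  if (abs(train + validation + test - 1) > 1e-8) {
    stop("split fractions must sum to 1")
  }
  structure(list(train = train, validation = validation, test = test,
                 seed = seed, stratified = stratified),
            class = "split_spec")
}

#' Partition labeled variants into train/validation/test
#'
#' Sizes follow the floor rule: validation and test receive
#' `floor(fraction * n)` variants each and the remainder goes to train
#' (1294 labeled variants split as 778/258/258). With stratification the
#' per-class allocation uses largest remainders so the totals are exact.
#'
#' @param labels Named label vector (`"D"`/`"ND"`; names are variant keys),
#'   or a data.frame with `variant` and `label` columns, or a
#'   `labeled_cohort`.
#' @param spec A [split_spec()].
#' @return Object of class `prof_split`: list of disjoint character vectors
#'   `train`, `validation`, `test`, plus the label lookup.
#' @export
split_data <- function(labels, spec = split_spec()) {
  labels <- as_label_vector(labels)
  n <- length(labels)
  if (n < 10L) stop("need at least 10 labeled variants to split")
  n_val <- floor(spec$validation * n)
  n_test <- floor(spec$test * n)

  set.seed(spec$seed)
  if (spec$stratified) {
    alloc_val <- largest_remainder(table(labels), n_val)
    alloc_test <- largest_remainder(table(labels), n_test)
    val <- test <- character()
    for (cls in names(alloc_val)) {
      idx <- sample(names(labels)[labels == cls])
      val <- c(val, idx[seq_len(alloc_val[[cls]])])
      test <- c(test, idx[alloc_val[[cls]] + seq_len(alloc_test[[cls]])])
    }
  } else {
    idx <- sample(names(labels))
    val <- idx[seq_len(n_val)]
    test <- idx[n_val + seq_len(n_test)]
  }
  train <- setdiff(names(labels), c(val, test))
  structure(list(train = train, validation = sort(val), test = sort(test),
                 labels = labels, spec = spec),
            class = "prof_split")
}

largest_remainder <- function(counts, total) {
  share <- as.numeric(counts) / sum(counts) * total
  base <- floor(share)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(counts))
}

as_label_vector <- function(labels) {
  if (inherits(labels, "labeled_cohort")) labels <- cohort_labels(labels)
  if (is.data.frame(labels)) {
    require_columns(labels, c("variant", "label"), "label table")
    labels <- stats::setNames(as.character(labels$label), labels$variant)
  }
  if (is.null(names(labels))) stop("labels must be named by variant key")
  labels
}

#' @export
print.prof_split <- function(x, ...) {
  cat(sprintf("60:20:20 split: train %d / validation %d / test %d (seed %d%s)\n",
              length(x$train), length(x$validation), length(x$test),
              x$spec$seed, if (x$spec$stratified) ", stratified" else ""))
  invisible(x)
}

#' Compare algorithms and feature sets over repeated tuned runs
#'
#' For every (algorithm, feature set) candidate, `n_runs` independently
#' seeded tuned models are trained on the training partition and scored on
#' the validation partition; mean validation AUC and accuracy summarize
#' each candidate.
#'
#' @param features Imputed `feature_matrix` covering all labeled variants.
#' @param split A `prof_split`.
#' @param algorithms Character vector out of `"gbm"`, `"rf"`.
#' @param feature_sets Character vector out of `"functional"`,
#'   `"computational"`, `"all"`.
#' @param n_runs Tuned runs per candidate (default 10).
#' @param n_candidates,cv_folds Passed to [prof_fit()].
#' @param seed Base seed; run r of a candidate uses `seed + r`.
#' @return Object of class `prof_comparison`: data.frame `runs` with one
#'   row per run, data.frame `means` with per-candidate mean AUC/accuracy.
#' @export
compare_models <- function(features, split,
                           algorithms = c("gbm", "rf"),
                           feature_sets = c("functional", "all"),
                           n_runs = 10L, n_candidates = 50L, cv_folds = 10L,
                           seed = 1L) {
  stopifnot(inherits(split, "prof_split"))
  runs <- list()
  for (alg in algorithms) {
    for (fs in feature_sets) {
      fm <- select_features(features, fs)
      xtr <- fm$values[split$train, , drop = FALSE]
      ytr <- split$labels[split$train]
      xval <- fm$values[split$validation, , drop = FALSE]
      yval <- split$labels[split$validation]
      for (r in seq_len(n_runs)) {
        model <- prof_fit(xtr, ytr, algorithm = alg,
                          n_candidates = n_candidates, cv_folds = cv_folds,
                          seed = seed + r)
        p <- predict(model, xval, type = "prob")
        cm <- confusion(yval, ifelse(p >= model$threshold, "D", "ND"))
        runs[[length(runs) + 1L]] <- data.frame(
          algorithm = alg, feature_set = fs, run = r,
          val_auc = auc_rank(p, yval),
          val_accuracy = summarize_confusion(cm)$accuracy,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  runs <- do.call(rbind, runs)
  means <- stats::aggregate(cbind(val_auc, val_accuracy) ~
                              algorithm + feature_set, runs, mean)
  structure(list(runs = runs, means = means), class = "prof_comparison")
}

#' @export
print.prof_comparison <- function(x, ...) {
  cat("Model comparison (means over", max(x$runs$run), "tuned runs)\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Select the best (algorithm, feature set) candidate
#'
#' Argmax of mean validation AUC; ties broken by mean validation accuracy,
#' then by algorithm order (gbm before rf).
#'
#' @param comparison A `prof_comparison` (or its `means` data.frame).
#' @return List with `algorithm` and `feature_set`.
#' @export
select_model <- function(comparison) {
  means <- if (inherits(comparison, "prof_comparison")) comparison$means
           else as.data.frame(comparison)
  require_columns(means, c("algorithm", "feature_set", "val_auc"),
                  "model comparison")
  if (is.null(means$val_accuracy)) means$val_accuracy <- 0
  alg_rank <- match(means$algorithm, c("gbm", "rf"))
  ord <- order(-means$val_auc, -means$val_accuracy, alg_rank)
  best <- means[ord[1L], ]
  list(algorithm = best$algorithm, feature_set = best$feature_set)
}

#' Final 80/20 fit and single test-set evaluation
#'
#' Refits the chosen model on train + validation (80% of the labeled
#' cohort) and evaluates it exactly once on the sealed test partition.
#'
#' @param features Imputed `feature_matrix`.
#' @param split A `prof_split`.
#' @param choice List with `algorithm` and `feature_set`, e.g. from
#'   [select_model()].
#' @param n_candidates,cv_folds,seed,threshold Passed to [prof_fit()].
#' @return Object of class `validation_report` (see
#'   [print.validation_report()]) with the fitted `model` attached.
#' @export
finalize_and_test <- function(features, split, choice,
                              n_candidates = 50L, cv_folds = 10L,
                              seed = 1L, threshold = 0.5) {
  stopifnot(inherits(split, "prof_split"))
  fm <- select_features(features, choice$feature_set)
  fit_ids <- c(split$train, split$validation)
  model <- prof_fit(fm$values[fit_ids, , drop = FALSE],
                    split$labels[fit_ids],
                    algorithm = choice$algorithm,
                    n_candidates = n_candidates, cv_folds = cv_folds,
                    seed = seed, threshold = threshold)
  model$feature_set <- choice$feature_set
  p <- predict(model, fm$values[split$test, , drop = FALSE], type = "prob")
  ytest <- split$labels[split$test]
  report <- validation_report(
    harness = "held-out test set",
    cm = confusion(ytest, ifelse(p >= model$threshold, "D", "ND")),
    auc = auc_rank(p, ytest),
    accounting = list(n_fit = length(fit_ids), n_test = length(split$test),
                      algorithm = choice$algorithm,
                      feature_set = choice$feature_set)
  )
  report$model <- model
  report
}

#' Score every variant of an enumerated space
#'
#' @param model A `prof_model`.
#' @param features Imputed `feature_matrix` covering the whole variant
#'   space (its training feature columns must all be present).
#' @return data.frame with one row per variant: `variant`, `probability`,
#'   `class`, `feature_set`, `algorithm`.
#' @export
predict_space <- function(model, features) {
  out <- predict(model, features, type = "both")
  out$feature_set <- model$feature_set
  out$algorithm <- model$algorithm
  out
}

#' Validation report container
#'
#' Bundles a confusion matrix, its summary statistics, an optional AUC and
#' per-harness accounting into one printable object; every validation
#' harness in the package returns one.
#'
#' @param harness Human-readable harness name.
#' @param cm A `confusion` object, or NULL.
#' @param auc Optional AUC.
#' @param accounting Named list of harness-specific counts.
#' @param extra Named list merged into the object.
#' @return Object of class `validation_report`.
#' @export
validation_report <- function(harness, cm = NULL, auc = NA_real_,
                              accounting = list(), extra = list()) {
  metrics <- if (!is.null(cm)) summarize_confusion(cm) else NULL
  structure(
    c(list(harness = harness, cm = cm, metrics = metrics, auc = auc,
           accounting = accounting), extra),
    class = "validation_report"
  )
}

#' @rdname validation_report
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", x$harness, "\n")
  if (!is.null(x$cm)) {
    cat(sprintf("  tp %d  tn %d  fp %d  fn %d\n",
                x$cm$tp, x$cm$tn, x$cm$fp, x$cm$fn))
    cat(sprintf("  accuracy %s  sensitivity %s  specificity %s\n",
                fmt_pct(x$metrics$accuracy), fmt_pct(x$metrics$sensitivity),
                fmt_pct(x$metrics$specificity)))
  }
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  if (length(x$accounting)) {
    cat("  accounting:",
        paste(names(x$accounting),
              vapply(x$accounting, function(v) paste(format(v), collapse = "/"),
                     character(1)),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Metrics block of a validation report as JSON
#'
#' @param report A `validation_report`.
#' @return JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  keep <- report[c("harness", "cm", "metrics", "auc", "accounting")]
  keep$cm <- unclass(keep$cm)
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null")
}
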