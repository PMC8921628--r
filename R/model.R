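#' Fit a tuned functionality classifier
#'
#' The central fitting function. Hyperparameters are chosen by random
#' search: `n_candidates` configurations are drawn from the search space,
#' each is scored by mean stratified k-fold cross-validated AUC on the
#' supplied data, and the best configuration is refit on all of it. Two
#' algorithms are supported: gradient boosting machines (`"gbm"`, via
#' xgboost) and random forests (`"rf"`, via ranger).
#'
#' The default GBM search space is tree depth 2-8, learning rate 0.01-0.3
#' (log-uniform), 100-1000 boosting rounds and row subsampling 0.5-1.0; the
#' RF space is mtry 1-p, minimum node size 1-10 at 500 trees. These are
#' package defaults, configurable through `search_space`.
#'
#' @param x Imputed [feature_matrix()] or numeric matrix (variants x
#'   features).
#' @param y Labels, `"D"` (deleterious, the positive class) / `"ND"`.
#' @param algorithm `"gbm"` or `"rf"`.
#' @param n_candidates Number of random hyperparameter draws (>= 1).
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling candidate draws, fold assignment
#'   and the stochastic parts of the ensembles; identical seed and inputs
#'   give identical fits and predictions.
#' @param threshold Decision threshold on the predicted probability of
#'   class D; class is D iff probability >= threshold.
#' @param search_space Optional list overriding parts of the default search
#'   space (see Details).
#' @return Object of class `prof_model`: `algorithm`, `feature_set`,
#'   `feature_names`, `params` (chosen hyperparameters), `cv` (per-candidate
#'   search log), `fit`, `threshold`, `importance` (normalized to sum 1),
#'   `seed`.
#' @seealso [predict.prof_model()], [variable_importance()], [split_data()],
#'   [finalize_and_test()]
#' @export
prof_fit <- function(x, y, algorithm = c("gbm", "rf"), n_candidates = 50L,
                     cv_folds = 10L, seed = 1L, threshold = 0.5,
                     search_space = NULL) {
  algorithm <- match.arg(algorithm)
  feature_set <- "user"
  if (inherits(x, "feature_matrix")) {
    groups <- unique(x$spec$group)
    feature_set <- if (length(groups) == 1L) groups else "all"
    x <- x$values
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values; impute first")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class ('", unique(y),
         "'); need both D and ND")
  }
  if (!all(y %in% c("D", "ND"))) stop("labels must be 'D' or 'ND'")
  stopifnot(n_candidates >= 1L, cv_folds >= 2L,
            threshold > 0, threshold < 1)
  y01 <- as.integer(y == "D")

  set.seed(seed)
  candidates <- draw_candidates(algorithm, n_candidates, ncol(x),
                                search_space)
  folds <- stratified_folds(y01, cv_folds)
  cv_auc <- vapply(candidates, function(par) {
    aucs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      fit <- fit_ensemble(x[tr, , drop = FALSE], y01[tr], algorithm, par,
                          seed = seed + k)
      p <- predict_ensemble(fit, x[!tr, , drop = FALSE])
      auc_rank(p, y01[!tr], positive = 1L)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))

  best <- which.max(cv_auc)
  params <- candidates[[best]]
  fit <- fit_ensemble(x, y01, algorithm, params, seed = seed)

  model <- structure(
    list(algorithm = algorithm, feature_set = feature_set,
         feature_names = colnames(x), params = params,
         cv = data.frame(candidate = seq_along(candidates),
                         cv_auc = cv_auc,
                         chosen = seq_along(candidates) == best),
         fit = fit, threshold = threshold, seed = seed,
         n_train = nrow(x), class_counts = table(y)),
    class = "prof_model"
  )
  model$importance <- compute_importance(model)
  model
}

draw_candidates <- function(algorithm, n, p, override = NULL) {
  space <- if (algorithm == "gbm") {
    list(max_depth = 2:8, eta = c(0.01, 0.3), nrounds = c(100L, 1000L),
         subsample = c(0.5, 1.0))
  } else {
    list(mtry = seq_len(p), min_node_size = 1:10, num_trees = 500L)
  }
  space[names(override)] <- override
  lapply(seq_len(n), function(i) {
    if (algorithm == "gbm") {
      list(
        max_depth = sample(space$max_depth, 1L),
        eta = exp(stats::runif(1, log(space$eta[1]), log(space$eta[2]))),
        nrounds = sample(seq(space$nrounds[1], space$nrounds[2]), 1L),
        subsample = stats::runif(1, space$subsample[1], space$subsample[2])
      )
    } else {
      list(
        mtry = sample(space$mtry, 1L),
        min_node_size = sample(space$min_node_size, 1L),
        num_trees = space$num_trees
      )
    }
  })
}

stratified_folds <- function(y01, k) {
  folds <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

fit_ensemble <- function(x, y01, algorithm, params, seed) {
  if (algorithm == "gbm") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample, nthread = 1,
                    seed = seed %% .Machine$integer.max),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
    list(kind = "gbm", booster = booster, feature_names = colnames(x))
  } else {
    rf <- ranger::ranger(
      x = x, y = factor(y01, levels = c(0L, 1L)),
      probability = TRUE, num.trees = params$num_trees, mtry = params$mtry,
      min.node.size = params$min_node_size, importance = "impurity",
      seed = seed, num.threads = 1
    )
    list(kind = "rf", forest = rf, feature_names = colnames(x))
  }
}

predict_ensemble <- function(fit, x) {
  if (fit$kind == "gbm") {
    predict(fit$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  } else {
    predict(fit$forest, data = x, num.threads = 1)$predictions[, "1"]
  }
}

#' Predict functionality class probabilities
#'
#' @param object A `prof_model`.
#' @param newdata Imputed `feature_matrix`, or numeric matrix whose columns
#'   cover the training features.
#' @param type `"prob"` for the probability of class D, `"class"` for
#'   thresholded `"D"`/`"ND"` labels, `"both"` for a data.frame.
#' @param ... Unused.
#' @return Named numeric vector, character vector, or data.frame
#'   (`variant`, `probability`, `class`).
#' @export
predict.prof_model <- function(object, newdata,
                               type = c("prob", "class", "both"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing)) {
    stop("prediction data is missing feature column(s): ",
         paste(missing, collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (anyNA(newdata)) stop("prediction data contains missing values; impute first")
  prob <- predict_ensemble(object$fit, newdata)
  names(prob) <- rownames(newdata)
  cls <- ifelse(prob >= object$threshold, "D", "ND")
  switch(type,
    prob = prob,
    class = cls,
    both = data.frame(variant = names(prob) %||% seq_along(prob),
                      probability = unname(prob), class = unname(cls),
                      stringsAsFactors = FALSE)
  )
}

compute_importance <- function(model) {
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  if (model$fit$kind == "gbm") {
    tab <- xgboost::xgb.importance(model = model$fit$booster)
    imp[tab$Feature] <- tab$Gain
  } else {
    raw <- model$fit$forest$variable.importance
    raw[raw < 0] <- 0
    imp[names(raw)] <- raw
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Variable importance of a fitted classifier
#'
#' Importances are non-negative and normalized to sum to one (gain share
#' for GBM, impurity decrease for RF). Grouped sums by assay/score source
#' are available via `by`.
#'
#' @param model A `prof_model`.
#' @param by Optional named character vector mapping feature name to a
#'   grouping key (e.g. the `source` column of a feature spec); importances
#'   are summed within groups.
#' @return Named numeric vector, decreasing.
#' @export
variable_importance <- function(model, by = NULL) {
  stopifnot(inherits(model, "prof_model"))
  imp <- model$importance
  if (!is.null(by)) {
    grp <- by[names(imp)]
    grp[is.na(grp)] <- "other"
    imp <- tapply(imp, grp, sum)
    imp <- stats::setNames(as.numeric(imp), names(imp))
  }
  sort(imp, decreasing = TRUE)
}

#' @export
print.prof_model <- function(x, ...) {
  cat("Functionality classifier (", toupper(x$algorithm), ", feature set: ",
      x$feature_set, ")\n", sep = "")
  cat("  trained on", x$n_train, "variants (",
      paste(names(x$class_counts), as.integer(x$class_counts),
            collapse = ", "), ")\n")
  cat("  tuned over", nrow(x$cv), "random candidate(s); best CV AUC",
      sprintf("%.4f", max(x$cv$cv_auc)), "\n")
  cat("  decision threshold:", x$threshold, "\n")
  invisible(x)
}

#' @export
summary.prof_model <- function(object, ...) {
  cat("Chosen hyperparameters:\n")
  for (k in names(object$params)) {
    cat(sprintf("  %-14s %s\n", k, format(object$params[[k]], digits = 4)))
  }
  cat("Top feature importances:\n")
  imp <- utils::head(variable_importance(object), 10L)
  for (k in names(imp)) cat(sprintf("  %-20s %.3f\n", k, imp[[k]]))
  invisible(object)
}

#' @export
plot.prof_model <- function(x, top = 15L, ...) {
  imp <- rev(utils::head(variable_importance(x), top))
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(imp, horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "normalized importance",
                    main = paste0(toupper(x$algorithm), " (",
                                  x$feature_set, " features)"), ...)
  invisible(x)
}
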