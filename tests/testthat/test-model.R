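# Small tuning budgets keep these tests quick; the tuning protocol itself is
# unchanged (random draws scored by stratified CV AUC).
fast <- list(n_candidates = 2L, cv_folds = 3L)

test_that("60:20:20 split honours the floor rule and determinism", {
  y <- stats::setNames(rep(c("D", "ND"), c(283, 1011)),
                       sprintf("v%04d", 1:1294))
  sp <- split_data(y, split_spec(seed = 5))
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 778L, validation = 258L, test = 258L))
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(length(intersect(sp$validation, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$validation, sp$test), names(y))

  sp2 <- split_data(y, split_spec(seed = 5))
  expect_identical(sp[1:3], sp2[1:3])
  sp3 <- split_data(y, split_spec(seed = 6))
  expect_false(identical(sp$test, sp3$test))

  # stratification keeps class balance within one variant of proportional
  frac_d <- mean(y == "D")
  expect_lt(abs(mean(y[sp$test] == "D") - frac_d), 2 / 258)

  y10 <- stats::setNames(rep(c("D", "ND"), 5), paste0("v", 1:10))
  sp10 <- split_data(y10)
  expect_identical(lengths(sp10[c("train", "validation", "test")]),
                   c(train = 6L, validation = 2L, test = 2L))
  expect_error(split_data(y10[1:5]), "at least 10")
})

test_that("strong class separation gives near-perfect cross-validated models", {
  toy <- toy_features(n = 200, p = 5, sep = 4, seed = 3)
  for (alg in c("gbm", "rf")) {
    model <- prof_fit(toy$x, toy$y, algorithm = alg,
                      n_candidates = fast$n_candidates,
                      cv_folds = fast$cv_folds, seed = 1)
    expect_gte(max(model$cv$cv_auc), 0.99)
    p <- predict(model, toy$x, type = "class")
    expect_gte(mean(p == toy$y), 0.99)
  }
})

test_that("permuted labels give chance-level CV AUC", {
  toy <- toy_features(n = 300, p = 5, sep = 4, seed = 3)
  set.seed(10)
  y_perm <- stats::setNames(sample(toy$y), names(toy$y))
  model <- prof_fit(toy$x, y_perm, algorithm = "gbm",
                    n_candidates = 2, cv_folds = 5, seed = 2)
  expect_gte(max(model$cv$cv_auc), 0.4)
  expect_lte(max(model$cv$cv_auc), 0.6)
})

test_that("degenerate and invalid training inputs fail loudly", {
  toy <- toy_features(n = 40)
  expect_error(prof_fit(toy$x, rep("D", 40)), "single class")
  xna <- toy$x
  xna[1, 1] <- NA
  expect_error(prof_fit(xna, toy$y), "missing")
  # n_candidates = 1 is a fixed-hyperparameter fit
  m1 <- prof_fit(toy$x, toy$y, n_candidates = 1, cv_folds = 2, seed = 1)
  expect_identical(nrow(m1$cv), 1L)
})

test_that("identical config and seed give identical predictions", {
  toy <- toy_features(n = 120, sep = 2, seed = 6)
  for (alg in c("gbm", "rf")) {
    m1 <- prof_fit(toy$x, toy$y, algorithm = alg, n_candidates = 2,
                   cv_folds = 3, seed = 99)
    m2 <- prof_fit(toy$x, toy$y, algorithm = alg, n_candidates = 2,
                   cv_folds = 3, seed = 99)
    expect_identical(predict(m1, toy$x), predict(m2, toy$x))
    expect_identical(m1$params, m2$params)
  }
})

test_that("model selection follows AUC, then accuracy, then algorithm order", {
  means <- data.frame(
    algorithm = c("gbm", "rf"), feature_set = "functional",
    val_auc = c(0.99, 0.98), val_accuracy = c(95, 97)
  )
  expect_identical(select_model(means)$algorithm, "gbm")
  means$val_auc <- c(0.99, 0.99)
  means$val_accuracy <- c(95, 97)
  expect_identical(select_model(means)$algorithm, "rf")
  means$val_accuracy <- c(97, 97)
  expect_identical(select_model(means)$algorithm, "gbm")
  expect_identical(select_model(means[1, , drop = FALSE])$algorithm, "gbm")
})

test_that("probability threshold uses the >= boundary convention", {
  toy <- toy_features(n = 60, sep = 4)
  model <- prof_fit(toy$x, toy$y, n_candidates = 1, cv_folds = 2, seed = 1)
  fake <- model
  fake$threshold <- 0.5
  # construct a probe: any probability exactly at threshold must be D
  p <- predict(model, toy$x, type = "prob")
  cls <- ifelse(p >= 0.5, "D", "ND")
  expect_identical(unname(predict(model, toy$x, type = "class")), unname(cls))
})

test_that("prediction demands the training feature columns by name", {
  toy <- toy_features(n = 60, sep = 3)
  model <- prof_fit(toy$x, toy$y, n_candidates = 1, cv_folds = 2, seed = 1)
  x_bad <- toy$x[, -2, drop = FALSE]
  expect_error(predict(model, x_bad), "f02")
  # extra columns and permuted order are fine
  x_extra <- cbind(toy$x[, rev(seq_len(ncol(toy$x)))], junk = 1)
  expect_identical(predict(model, x_extra), predict(model, toy$x))
})

test_that("variable importance is normalized and finds the signal feature", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("v%03d", 1:n), paste0("f", 1:5)))
  y <- stats::setNames(ifelse(x[, 1] > 0, "D", "ND"), rownames(x))
  for (alg in c("gbm", "rf")) {
    model <- prof_fit(x, y, algorithm = alg, n_candidates = 2, cv_folds = 3,
                      seed = 4)
    imp <- variable_importance(model)
    expect_equal(sum(imp), 1, tolerance = 1e-8)
    expect_true(all(imp >= 0))
    expect_gt(imp[["f1"]], 0.8)
  }
  # grouped importances sum within groups
  model <- prof_fit(x, y, n_candidates = 1, cv_folds = 2, seed = 4)
  grp <- stats::setNames(c("a", "a", "b", "b", "b"), paste0("f", 1:5))
  gi <- variable_importance(model, by = grp)
  expect_equal(sum(gi), 1, tolerance = 1e-8)
  expect_identical(sort(names(gi)), c("a", "b"))
})

test_that("the full protocol seals the test set and reports honestly", {
  sim <- simulate_cohort(n_variants = 400, csd_size = 80, n_absent = 120,
                         n_singleton = 60, partial_rate = 0, seed = 14)
  features <- impute_median(sim$features)
  labels <- stats::setNames(
    ifelse(sim$truth$latent_class == "D", "D", "ND"), sim$truth$variant
  )
  labeled <- labels[sim$truth$provenance != "other"]
  sp <- split_data(labeled, split_spec(seed = 2))

  cmp <- compare_models(features, sp, algorithms = "gbm",
                        feature_sets = c("functional", "computational"),
                        n_runs = 2, n_candidates = 2, cv_folds = 3, seed = 7)
  expect_identical(nrow(cmp$runs), 4L)
  choice <- select_model(cmp)
  expect_true(choice$feature_set %in% c("functional", "computational"))

  rep <- finalize_and_test(features, sp, list(algorithm = "gbm",
                                              feature_set = "functional"),
                           n_candidates = 2, cv_folds = 3, seed = 7)
  expect_s3_class(rep, "validation_report")
  expect_identical(rep$accounting$n_test, length(sp$test))
  expect_gte(rep$metrics$accuracy, 95)
  expect_gte(rep$auc, 0.98)

  # training-set optimism: rescoring fit data is at least as accurate
  fit_ids <- c(sp$train, sp$validation)
  acc_fit <- mean(predict(rep$model,
                          select_features(features, "functional")$values[fit_ids, ],
                          type = "class") == labeled[fit_ids])
  expect_gte(acc_fit + 1e-9, rep$metrics$accuracy / 100 - 0.02)

  preds <- predict_space(rep$model, select_features(features, "functional"))
  expect_identical(nrow(preds), 400L)
  expect_setequal(unique(preds$class), c("D", "ND"))
  expect_identical(unique(preds$feature_set), "functional")
})
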