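# Training, grid search, cross-validation, classification and persistence.

# small labeled table split cleanly by one feature threshold
separable_table <- function(n = 60, p = 10, seed = 61) {
  set.seed(seed)
  y <- rep(c("affecting", "neutral"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 1] <- ifelse(y == "affecting", 1, -1) + rnorm(n, sd = 0.1)
  tab <- data.frame(variant_id = paste0("v", 1:n), label = y, x,
                    check.names = FALSE)
  attr(tab, "registry_hash") <- "toy-registry"
  tab
}

test_that("a separable table is fit perfectly by the tree model", {
  tab <- separable_table()
  m <- train_model(tab, "gradient_boosting", seed = 1)
  expect_s3_class(m, "TrainedModel")
  prob <- predict_prob(m, tab)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_equal(mean((prob >= 0.5) == (tab$label == "affecting")), 1)
  expect_gt(m$importances[["f1"]], max(m$importances[-1]))
})

test_that("all three algorithms train, predict in [0,1], and rank f1 first", {
  tab <- separable_table()
  for (alg in c("gradient_boosting", "linear_svm", "random_forest")) {
    m <- train_model(tab, alg, seed = 2)
    prob <- predict_prob(m, tab)
    expect_true(all(prob >= 0 & prob <= 1))
    expect_gt(auroc(prob, as.integer(tab$label == "affecting")), 0.95)
    expect_identical(names(which.max(m$importances)), "f1")
  }
})

test_that("a single-point grid returns exactly those hyperparameters", {
  tab <- separable_table()
  grid <- data.frame(learning_rate = 0.07, num_leaves = 9,
                     n_estimators = 55, min_child_samples = 4)
  m <- grid_search_train(tab, "gradient_boosting", grid = grid, seed = 3)
  expect_equal(m$hyperparameters[names(grid)], as.list(grid))
  expect_identical(nrow(m$grid_results), 1L)
  expect_error(grid_search_train(tab, grid = grid[0, ]), "empty grid")
})

test_that("grid search is deterministic under a fixed seed", {
  tab <- separable_table(n = 40)
  grid <- expand.grid(learning_rate = c(0.05, 0.2), num_leaves = c(7, 15),
                      n_estimators = 50, min_child_samples = 5)
  m1 <- grid_search_train(tab, "gradient_boosting", grid = grid, seed = 4)
  m2 <- grid_search_train(tab, "gradient_boosting", grid = grid, seed = 4)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_equal(m1$grid_results$mean_auroc, m2$grid_results$mean_auroc)
})

test_that("stratified folds partition every row exactly once", {
  tab <- separable_table(n = 46)
  cv <- kfold_cross_validate(tab, "gradient_boosting", k = 5, seed = 5,
                             params = list(n_estimators = 40))
  expect_identical(nrow(cv$per_fold), 5L)
  # each row is scored in exactly one held-out fold
  expect_length(cv$pooled$scores, 46)
  total <- Reduce(`+`, lapply(cv$fold_counts, function(cc) {
    cc$TP + cc$FP + cc$TN + cc$FN
  }))
  expect_identical(total, 46L)
  # separable data: near-perfect mean accuracy
  expect_gt(cv$summary$mean[cv$summary$metric == "accuracy"], 0.95)
  expect_error(kfold_cross_validate(tab[1:8, ], k = 10), "fewer than k")
})

test_that("label-shuffled data scores near-chance AUROC", {
  set.seed(66)
  n <- 300
  tab <- data.frame(variant_id = paste0("v", 1:n),
                    label = sample(rep(c("affecting", "neutral"), n / 2)),
                    matrix(rnorm(n * 10), n, 10,
                           dimnames = list(NULL, paste0("f", 1:10))),
                    check.names = FALSE)
  cv <- kfold_cross_validate(tab, "gradient_boosting", k = 5, seed = 6,
                             params = list(n_estimators = 60))
  expect_lt(abs(cv$summary$mean[cv$summary$metric == "auroc"] - 0.5), 0.1)
})

test_that("classification applies the 0.5 threshold inclusively", {
  cnt <- fexsplice:::counts_at_threshold(c(0.49, 0.50, 0.51, 0.10),
                                         c(0L, 1L, 1L, 0L))
  expect_identical(cnt$TP, 2L)  # 0.50 counts as affecting
  expect_identical(cnt$FP, 0L)
  expect_identical(cnt$TN, 2L)  # 0.49 stays neutral
  tab <- separable_table()
  m <- train_model(tab, "gradient_boosting", seed = 7)
  res <- classify(m, tab[1, ])
  expect_identical(res$call, ifelse(res$probability >= 0.5,
                                    "affecting", "neutral"))
})

test_that("classify refuses a registry-hash mismatch", {
  tab <- separable_table()
  m <- train_model(tab, "gradient_boosting", seed = 8)
  v <- as.numeric(tab[1, paste0("f", 1:10)])
  names(v) <- paste0("f", 1:10)
  attr(v, "registry_hash") <- "other-registry"
  expect_error(classify(m, v), "hash")
  attr(v, "registry_hash") <- "toy-registry"
  expect_identical(classify(m, v)$call, "affecting")
})

test_that("saved gradient-boosting models reload and predict identically", {
  tab <- separable_table()
  m <- train_model(tab, "gradient_boosting", seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$registry_hash, m$registry_hash)
  expect_equal(m2$hyperparameters, m$hyperparameters)
  expect_equal(predict_prob(m2, tab), predict_prob(m, tab))
  mrf <- train_model(tab, "random_forest", seed = 9)
  expect_error(save_model(mrf, path), "gradient-boosting")
})

test_that("recursive elimination keeps informative features", {
  set.seed(71)
  n <- 40L; p <- 10L
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  # jointly informative pair: neither feature separates the classes alone
  y <- ifelse(x[, 1] + x[, 2] > 0, "affecting", "neutral")
  tab <- data.frame(variant_id = paste0("v", 1:n), label = y, x,
                    check.names = FALSE)
  rfe <- rfe_loocv(tab, "gradient_boosting", seed = 10, cv = "kfold", k = 5,
                   params = list(n_estimators = 40, num_leaves = 7))
  expect_identical(nrow(rfe$trace), p - 1L)
  expect_identical(rfe$trace$n_features, seq(p, 2L))
  expect_true(all(c("f1", "f2") %in% rfe$best_subset))
  # argmax property: the best subset scores at least as well as the full set
  expect_gte(rfe$best_balanced_accuracy, rfe$trace$balanced_accuracy[1])
  # retained sets are nested by construction
  for (i in 2:nrow(rfe$trace)) {
    expect_true(all(rfe$trace$retained[[i]] %in% rfe$trace$retained[[i - 1]]))
  }
})
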