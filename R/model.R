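# Classifier training and evaluation: gradient boosting (xgboost) plus
# linear-SVM and random-forest baselines, grid search by inner-CV AUROC,
# stratified k-fold cross-validation, LOOCV-driven recursive feature
# elimination, and thresholded classification.

POSITIVE_LABEL <- "affecting"
PROB_THRESHOLD <- 0.5

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

table_xy <- function(table) {
  y <- table$label
  if (is.null(y) || anyNA(y)) stop("table must have a complete label column",
                                   call. = FALSE)
  y <- as.integer(y == POSITIVE_LABEL)
  x <- as.matrix(feature_columns(table))
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

default_params <- function(algorithm) {
  switch(algorithm,
    gradient_boosting = list(learning_rate = 0.1, num_leaves = 15,
                             n_estimators = 150, min_child_samples = 5),
    linear_svm = list(C = 1),
    random_forest = list(n_trees = 300, max_features = "sqrt"))
}

#' Default hyperparameter grids
#'
#' Small exhaustive grids sized for datasets of a few hundred variants.
#'
#' @param algorithm one of `"gradient_boosting"`, `"linear_svm"`,
#'   `"random_forest"`.
#' @return data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm = c("gradient_boosting", "linear_svm",
                                       "random_forest")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    gradient_boosting = expand.grid(learning_rate = c(0.05, 0.1),
                                    num_leaves = c(7, 15, 31),
                                    n_estimators = c(100, 300),
                                    min_child_samples = c(5, 10)),
    linear_svm = expand.grid(C = c(0.01, 0.1, 1, 10)),
    random_forest = expand.grid(n_trees = 300,
                                max_features = c("sqrt", "0.3"),
                                stringsAsFactors = FALSE))
}

fit_algorithm <- function(x, y, algorithm, params, seed) {
  with_seed(seed, switch(algorithm,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$learning_rate,
                      max_leaves = params$num_leaves,
                      max_depth = 0, grow_policy = "lossguide",
                      tree_method = "hist",
                      # min_child_weight is a hessian sum; for logistic loss
                      # each sample contributes at most 1/4, so this enforces
                      # at least min_child_samples data points per leaf
                      min_child_weight = params$min_child_samples / 4,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
    },
    linear_svm = e1071::svm(x, factor(y, levels = c(0, 1)),
                            kernel = "linear", cost = params$C,
                            probability = TRUE, scale = FALSE),
    random_forest = {
      mtry <- if (identical(params$max_features, "sqrt")) {
        max(1L, floor(sqrt(ncol(x))))
      } else max(1L, floor(as.numeric(params$max_features) * ncol(x)))
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = params$n_trees, mtry = mtry)
    },
    stop("unknown algorithm '", algorithm, "'", call. = FALSE)))
}

predict_fit <- function(fit, algorithm, x) {
  switch(algorithm,
    gradient_boosting = predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    linear_svm = {
      p <- attr(predict(fit, x, probability = TRUE), "probabilities")
      unname(p[, "1"])
    },
    random_forest = unname(predict(fit, x, type = "prob")[, "1"]))
}

fit_importance <- function(fit, algorithm, feature_names) {
  out <- setNames(numeric(length(feature_names)), feature_names)
  if (algorithm == "gradient_boosting") {
    imp <- xgboost::xgb.importance(model = fit)  # split-gain importance
    out[imp$Feature] <- imp$Gain
  } else if (algorithm == "random_forest") {
    gi <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    out[names(gi)] <- gi
  } else if (algorithm == "linear_svm") {
    w <- drop(t(fit$coefs) %*% fit$SV)  # |weight| as importance
    out[names(w)] <- abs(w)
  } else {
    stop("importance unavailable for '", algorithm, "'", call. = FALSE)
  }
  out
}

#' Train a classifier on a feature table
#'
#' @param table labeled feature table from [extract_feature_table()] (label
#'   values `"affecting"` / `"neutral"`).
#' @param algorithm `"gradient_boosting"` (default), `"linear_svm"` or
#'   `"random_forest"`.
#' @param params named list of hyperparameters overriding the defaults
#'   (gradient boosting: `learning_rate`, `num_leaves`, `n_estimators`,
#'   `min_child_samples`; linear SVM: `C`; random forest: `n_trees`,
#'   `max_features`).
#' @param seed integer RNG seed recorded in the model.
#' @return object of class `TrainedModel` with the fitted classifier,
#'   hyperparameters, feature subset, per-feature importances and the
#'   registry hash of the training table.
#' @export
train_model <- function(table, algorithm = c("gradient_boosting", "linear_svm",
                                             "random_forest"),
                        params = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  d <- table_xy(table)
  if (min(table(d$y)) < 2L) stop("need at least 2 rows per class", call. = FALSE)
  hp <- utils::modifyList(default_params(algorithm), as.list(params))
  fit <- fit_algorithm(d$x, d$y, algorithm, hp, seed)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 features = colnames(d$x),
                 importances = fit_importance(fit, algorithm, colnames(d$x)),
                 registry_hash = attr(table, "registry_hash"),
                 seed = as.integer(seed), format_version = "1.0", fit = fit),
            class = "TrainedModel")
}

#' Predict probabilities for a feature table
#'
#' @param model a `TrainedModel`.
#' @param table feature table (label column, if present, is ignored).
#' @return numeric vector of splicing-affecting probabilities.
#' @export
predict_prob <- function(model, table) {
  x <- as.matrix(feature_columns(table))
  storage.mode(x) <- "double"
  miss <- setdiff(model$features, colnames(x))
  if (length(miss) > 0L) {
    stop("table lacks model feature(s): ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  predict_fit(model$fit, model$algorithm, x[, model$features, drop = FALSE])
}

#' Classify one feature vector
#'
#' A variant is called splicing-affecting when its predicted probability is
#' at least 0.5, and neutral otherwise.
#'
#' @param model a `TrainedModel`.
#' @param vector a feature vector from [extract_features()] (its registry
#'   hash must match the model's), or a one-row feature table.
#' @return list with `probability` and `call` (`"affecting"`/`"neutral"`).
#' @export
classify <- function(model, vector) {
  if (is.numeric(vector)) {
    h <- attr(vector, "registry_hash")
    tab <- as.data.frame(as.list(vector), check.names = FALSE)
    attr(tab, "registry_hash") <- h
  } else tab <- vector
  h <- attr(tab, "registry_hash")
  if (!is.null(model$registry_hash) && !is.null(h) &&
      !identical(h, model$registry_hash)) {
    stop("feature registry hash does not match the model's", call. = FALSE)
  }
  p <- predict_prob(model, tab)
  list(probability = p,
       call = ifelse(p >= PROB_THRESHOLD, "affecting", "neutral"))
}

# stratified fold assignment: shuffle within class, deal out cyclically
stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (min(table(y)) < k) {
    stop("fewer than k members in a class; folds would lack a class",
         call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

counts_at_threshold <- function(prob, y, threshold = PROB_THRESHOLD) {
  pred <- as.integer(prob >= threshold)
  confusion_counts(TP = sum(pred == 1L & y == 1L),
                   FP = sum(pred == 1L & y == 0L),
                   TN = sum(pred == 0L & y == 0L),
                   FN = sum(pred == 0L & y == 1L))
}

roc_curve_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[keep],
             fpr = fp[keep] / sum(1L - y), tpr = tp[keep] / sum(y))
}

#' Stratified k-fold cross-validation
#'
#' Trains on k-1 folds and evaluates on the held-out fold, reporting
#' per-fold confusion counts at the 0.5 threshold, the seven statistics plus
#' AUROC/AUPRC, their mean and SD across folds, per-fold and pooled ROC /
#' precision-recall curve points with the 0.5-threshold operating point
#' marked, and (for tree models) fold-averaged feature importances.
#'
#' @param table labeled feature table.
#' @param algorithm classifier (see [train_model()]).
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and training.
#' @param params hyperparameter overrides passed to [train_model()].
#' @return object of class `MetricsReport`.
#' @export
kfold_cross_validate <- function(table, algorithm = "gradient_boosting",
                                 k = 10L, seed = 1L, params = NULL) {
  d <- table_xy(table)
  folds <- stratified_folds(d$y, k, seed)
  per_fold <- vector("list", k)
  fold_counts <- vector("list", k)
  roc_list <- pr_list <- op_list <- vector("list", k)
  imp <- matrix(0, nrow = k, ncol = ncol(d$x),
                dimnames = list(NULL, colnames(d$x)))
  pooled_scores <- numeric(length(d$y)); pooled_y <- d$y
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    sub <- table[tr, , drop = FALSE]
    attr(sub, "registry_hash") <- attr(table, "registry_hash")
    model <- train_model(sub, algorithm, params = params, seed = seed + f)
    prob <- predict_prob(model, table[te, , drop = FALSE])
    pooled_scores[te] <- prob
    cnt <- counts_at_threshold(prob, d$y[te])
    fold_counts[[f]] <- cnt
    per_fold[[f]] <- c(compute_metrics(cnt),
                       auroc = auroc(prob, d$y[te]),
                       auprc = auprc(prob, d$y[te]))
    roc_list[[f]] <- cbind(fold = f, roc_curve_points(prob, d$y[te]))
    pr_list[[f]] <- cbind(fold = f, pr_points(prob, d$y[te]))
    m <- compute_metrics(cnt)
    op_list[[f]] <- data.frame(fold = f,
                               fpr = 1 - m[["specificity"]],
                               tpr = m[["recall"]],
                               recall = m[["recall"]],
                               precision = m[["precision"]])
    imp[f, ] <- model$importances
  }
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(metric = colnames(per_fold),
                        mean = apply(per_fold, 2, mean, na.rm = TRUE),
                        sd = apply(per_fold, 2, sd, na.rm = TRUE),
                        row.names = NULL)
  pooled_m <- compute_metrics(counts_at_threshold(pooled_scores, pooled_y))
  structure(list(
    algorithm = algorithm, k = k, seed = as.integer(seed),
    fold_counts = fold_counts, per_fold = as.data.frame(per_fold),
    summary = summary,
    roc_points = do.call(rbind, roc_list), pr_points = do.call(rbind, pr_list),
    operating_points = do.call(rbind, op_list),
    pooled = list(scores = pooled_scores, labels = pooled_y,
                  auroc = auroc(pooled_scores, pooled_y),
                  auprc = auprc(pooled_scores, pooled_y),
                  roc_points = roc_curve_points(pooled_scores, pooled_y),
                  pr_points = pr_points(pooled_scores, pooled_y),
                  operating_point = data.frame(
                    fpr = 1 - pooled_m[["specificity"]],
                    tpr = pooled_m[["recall"]],
                    recall = pooled_m[["recall"]],
                    precision = pooled_m[["precision"]])),
    importance_mean = colMeans(imp)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: %s, %d-fold CV (seed %d)\n", x$algorithm, x$k,
              x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Grid-search training
#'
#' Exhaustive search over a hyperparameter grid, selecting the combination
#' with the highest inner-cross-validation mean AUROC (ties go to the first
#' grid row), then refitting on the full table.
#'
#' @param table labeled feature table.
#' @param algorithm classifier.
#' @param grid data.frame of hyperparameter combinations; defaults to
#'   [default_grid()].
#' @param seed RNG seed (inner folds and training).
#' @param inner_k inner CV fold count (default 5).
#' @return `TrainedModel` with `$grid_results` (per-combination mean AUROC)
#'   attached.
#' @export
grid_search_train <- function(table, algorithm = "gradient_boosting",
                              grid = default_grid(algorithm), seed = 1L,
                              inner_k = 5L) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  d <- table_xy(table)
  folds <- stratified_folds(d$y, inner_k, seed)
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      fit <- fit_algorithm(d$x[tr, , drop = FALSE], d$y[tr], algorithm,
                           utils::modifyList(default_params(algorithm), hp),
                           seed + f)
      auroc(predict_fit(fit, algorithm, d$x[!tr, , drop = FALSE]), d$y[!tr])
    }, numeric(1))
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)
  model <- train_model(table, algorithm,
                       params = as.list(grid[best, , drop = FALSE]),
                       seed = seed)
  model$grid_results <- cbind(grid, mean_auroc = mean_auc)
  model
}

# leave-one-out (or k-fold) balanced accuracy of one feature subset
cv_balanced_accuracy <- function(x, y, algorithm, params, seed,
                                 cv = "loo", k = 10L) {
  n <- length(y)
  folds <- if (cv == "loo") seq_len(n) else stratified_folds(y, k, seed)
  prob <- numeric(n)
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- fit_algorithm(x[tr, , drop = FALSE], y[tr], algorithm, params,
                         seed + f)
    prob[!tr] <- predict_fit(fit, algorithm, x[!tr, , drop = FALSE])
  }
  balanced_accuracy(counts_at_threshold(prob, y))
}

#' Recursive feature elimination with cross-validated balanced accuracy
#'
#' Starting from the full feature set, iteratively removes the feature with
#' the lowest importance in a full-data fit, scoring each subset by the
#' balanced accuracy (mean of recall and specificity at the 0.5 threshold)
#' of leave-one-out cross-validation. Returns the full trace (subset sizes
#' N, N-1, ..., 2) and the subset maximising balanced accuracy; ties go to
#' the smaller subset.
#'
#' @param table labeled feature table.
#' @param algorithm classifier providing importances.
#' @param seed RNG seed.
#' @param params hyperparameter overrides.
#' @param cv `"loo"` (default) or `"kfold"` for the subset scoring.
#' @param k fold count when `cv = "kfold"`.
#' @return object of class `RFETrace`: `trace` (data.frame with
#'   `n_features`, `balanced_accuracy`, list-column `retained`),
#'   `best_subset`, `best_balanced_accuracy`.
#' @export
rfe_loocv <- function(table, algorithm = "gradient_boosting", seed = 1L,
                      params = NULL, cv = c("loo", "kfold"), k = 10L) {
  cv <- match.arg(cv)
  d <- table_xy(table)
  hp <- utils::modifyList(default_params(algorithm), as.list(params))
  current <- colnames(d$x)
  sizes <- seq(length(current), 2L)
  trace <- data.frame(n_features = sizes, balanced_accuracy = NA_real_)
  trace$retained <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    xs <- d$x[, current, drop = FALSE]
    trace$balanced_accuracy[i] <-
      cv_balanced_accuracy(xs, d$y, algorithm, hp, seed, cv = cv, k = k)
    trace$retained[[i]] <- current
    fit <- fit_algorithm(xs, d$y, algorithm, hp, seed)
    imp <- fit_importance(fit, algorithm, current)
    current <- current[-which.min(imp)]  # ties: first (registry order)
  }
  # argmax balanced accuracy; ties -> fewer features (later trace rows)
  best_i <- max(which(trace$balanced_accuracy ==
                        max(trace$balanced_accuracy)))
  structure(list(trace = trace,
                 best_subset = trace$retained[[best_i]],
                 best_balanced_accuracy = trace$balanced_accuracy[best_i],
                 algorithm = algorithm, seed = as.integer(seed)),
            class = "RFETrace")
}

#' Save / load a trained gradient-boosting model
#'
#' Writes a versioned JSON container embedding the registry hash, seed,
#' hyperparameters, feature subset, importances and the booster's own JSON
#' dump. Only gradient-boosting models have a text-serialisable booster.
#'
#' @param model a `TrainedModel` with `algorithm = "gradient_boosting"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TrainedModel"))
  if (model$algorithm != "gradient_boosting") {
    stop("only gradient-boosting models are text-serialisable", call. = FALSE)
  }
  payload <- list(
    format_version = model$format_version, algorithm = model$algorithm,
    hyperparameters = model$hyperparameters, features = model$features,
    importances = as.list(model$importances),
    registry_hash = model$registry_hash, seed = model$seed,
    booster_json = rawToChar(xgboost::xgb.save.raw(model$fit,
                                                   raw_format = "json")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- xgboost::xgb.load.raw(charToRaw(p$booster_json))
  structure(list(algorithm = p$algorithm,
                 hyperparameters = as.list(p$hyperparameters),
                 features = p$features,
                 importances = unlist(p$importances),
                 registry_hash = p$registry_hash, seed = p$seed,
                 format_version = p$format_version, fit = fit),
            class = "TrainedModel")
}
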