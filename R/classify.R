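#' Importance-threshold feature selection
#'
#' Scores every feature outside the `always_keep` families with the
#' impurity-decrease importance of a seeded tree ensemble (500 trees),
#' normalizes importances to fractions summing to 1 over the scored
#' features, and keeps those at or above the threshold (default 0.5%).
#' The `always_keep` families (GLCM by default, whose per-state trends are
#' interpretable on their own) bypass scoring and are always retained.
#'
#' @param features Numeric matrix (rows = images) with feature-name column
#'   names.
#' @param labels Class labels (two or more classes).
#' @param threshold Importance fraction cutoff; a tie at exactly the
#'   threshold is retained (default 0.005).
#' @param always_keep Character vector of family prefixes kept without
#'   scoring (default `"glcm"`).
#' @param num_trees Ensemble size (default 500).
#' @param seed Seed for the ensemble.
#' @return An object of class `selection_result`: list with `kept_names`,
#'   `importances` (named fractions over scored features), `threshold`,
#'   `always_keep`.
#' @export
importance_selection <- function(features, labels, threshold = 0.005,
                                 always_keep = "glcm", num_trees = 500,
                                 seed = 1) {
  if (!is.matrix(features) || nrow(features) == 0)
    stop("importance_selection: features must be a nonempty matrix")
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("importance_selection: need at least 2 classes")
  fam <- feature_family(colnames(features))
  scored <- which(!(fam %in% always_keep))
  kept <- colnames(features)[fam %in% always_keep]
  imp_frac <- numeric(0)
  if (length(scored) > 0) {
    fit <- ranger::ranger(x = features[, scored, drop = FALSE], y = labels,
                          num.trees = num_trees, importance = "impurity",
                          seed = seed, num.threads = 1)
    imp <- fit$variable.importance
    total <- sum(imp)
    if (total <= 0) stop("importance_selection: all importances are zero")
    imp_frac <- imp / total
    kept <- c(kept, names(imp_frac)[imp_frac >= threshold])
  }
  structure(list(kept_names = kept, importances = imp_frac,
                 threshold = threshold, always_keep = always_keep),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features kept (threshold %.3g, always: %s)\n",
              length(x$kept_names), x$threshold,
              paste(x$always_keep, collapse = ",")))
  invisible(x)
}

#' Stratified split and z-score standardization
#'
#' Splits the feature matrix into stratified train/test sets (default 4:1)
#' and z-scores every column with the training-set mean and standard
#' deviation (applied to both sets; constant columns are centered only).
#'
#' @param features Numeric matrix.
#' @param labels Class labels.
#' @param test_fraction Test share (default 0.2).
#' @param seed Seed for the split.
#' @return List with `x_train`, `y_train`, `x_test`, `y_test`,
#'   `scaler` (list `center`, `scale`), `train_idx`, `test_idx`.
#' @export
split_and_standardize <- function(features, labels, test_fraction = 0.2,
                                  seed = 1) {
  labels <- factor(labels)
  if (any(table(labels) < 2))
    stop("split_and_standardize: every class needs at least 2 members")
  idx_test <- with_seed(seed, {
    unlist(lapply(levels(labels), function(l) {
      ids <- which(labels == l)
      sample(ids, max(1L, round(length(ids) * test_fraction)))
    }))
  })
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(nrow(features)), idx_test)
  center <- colMeans(features[idx_train, , drop = FALSE])
  scale_ <- apply(features[idx_train, , drop = FALSE], 2, sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  std <- function(m) sweep(sweep(m, 2, center), 2, scale_, "/")
  list(x_train = std(features[idx_train, , drop = FALSE]),
       y_train = droplevels(labels[idx_train]),
       x_test = std(features[idx_test, , drop = FALSE]),
       y_test = droplevels(labels[idx_test]),
       scaler = list(center = center, scale = scale_),
       train_idx = idx_train, test_idx = idx_test)
}

#' Hyperparameter grids
#'
#' `default_grid()` defines the reference tuning ranges:
#' * KNN: `n_neighbors` 3–30, `weights` uniform/distance (56 combinations);
#' * SVM: `C` 0.01 to 5.01 step 0.05, `gamma` 0.01 to 10.01 step 0.1,
#'   kernel linear/rbf (20,402 combinations);
#' * random forest: `n_estimators` 50–201, `max_features` sqrt/log2,
#'   `max_depth` 5–10 or unlimited (`NA`), `min_samples_split` 2–5
#'   (8,512 combinations).
#'
#' `reduced_grid()` is a small subset of the same ranges for quick runs.
#'
#' @param model_type `"knn"`, `"svm"` or `"random_forest"`.
#' @return A data.frame, one row per hyperparameter combination.
#' @examples
#' nrow(default_grid("knn"))  # 56
#' @export
default_grid <- function(model_type = c("knn", "svm", "random_forest")) {
  model_type <- match.arg(model_type)
  switch(model_type,
    knn = expand.grid(n_neighbors = 3:30,
                      weights = c("uniform", "distance"),
                      stringsAsFactors = FALSE),
    svm = expand.grid(C = seq(0.01, 5.01, by = 0.05),
                      gamma = seq(0.01, 10.01, by = 0.1),
                      kernel = c("linear", "rbf"),
                      stringsAsFactors = FALSE),
    random_forest = expand.grid(n_estimators = 50:201,
                                max_features = c("sqrt", "log2"),
                                max_depth = c(5:10, NA),
                                min_samples_split = 2:5,
                                stringsAsFactors = FALSE))
}

#' @rdname default_grid
#' @export
reduced_grid <- function(model_type = c("knn", "svm", "random_forest")) {
  model_type <- match.arg(model_type)
  switch(model_type,
    knn = expand.grid(n_neighbors = c(3, 9, 15, 21, 27),
                      weights = c("uniform", "distance"),
                      stringsAsFactors = FALSE),
    svm = expand.grid(C = c(0.01, 0.51, 1.01, 2.51, 5.01),
                      gamma = c(0.01, 0.51, 1.01, 5.01),
                      kernel = c("linear", "rbf"),
                      stringsAsFactors = FALSE),
    random_forest = expand.grid(n_estimators = c(50, 100, 150, 201),
                                max_features = c("sqrt", "log2"),
                                max_depth = c(10, NA),
                                min_samples_split = 2,
                                stringsAsFactors = FALSE))
}

# Fit one model with the given hyperparameter row. `positive` is the class
# treated as positive downstream (post-intervention state).
.fit_one <- function(model_type, params, x, y, positive, seed = 1) {
  y <- factor(y)
  fit <- switch(model_type,
    knn = list(x = x, y = y, k = params$n_neighbors,
               weights = params$weights),
    svm = e1071::svm(x, y,
                     kernel = if (params$kernel == "rbf") "radial" else "linear",
                     cost = params$C, gamma = params$gamma, scale = FALSE),
    random_forest = {
      p <- ncol(x)
      mtry <- if (params$max_features == "sqrt") max(1L, floor(sqrt(p)))
              else max(1L, floor(log2(p)))
      ranger::ranger(x = x, y = y, num.trees = params$n_estimators,
                     mtry = min(mtry, p),
                     max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
                     min.node.size = max(1, params$min_samples_split - 1),
                     probability = TRUE, seed = seed, num.threads = 1)
    })
  structure(list(type = model_type, params = params, fit = fit,
                 levels = levels(y), positive = positive),
            class = "ecs_model")
}

# Score for the positive class plus hard labels, for any ecs_model.
.predict_scores <- function(model, x) {
  pos <- model$positive
  neg <- setdiff(model$levels, pos)[1]
  if (model$type == "knn") {
    tr <- model$fit
    d2 <- outer(rowSums(x^2), rowSums(tr$x^2), "+") - 2 * x %*% t(tr$x)
    d2 <- pmax(d2, 0)
    k <- tr$k
    score <- numeric(nrow(x))
    lab <- character(nrow(x))
    is_pos <- tr$y == pos
    for (i in seq_len(nrow(x))) {
      ord <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
      w <- if (tr$weights == "distance") 1 / (sqrt(d2[i, ord]) + 1e-12)
           else rep(1, length(ord))
      score[i] <- sum(w * is_pos[ord]) / sum(w)
      lab[i] <- if (score[i] > 0.5) pos
                else if (score[i] < 0.5) neg
                else as.character(tr$y[ord[1]])   # tie: nearest neighbor
    }
    list(score = score, label = factor(lab, levels = model$levels))
  } else if (model$type == "svm") {
    pr <- predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # column name "A/B": positive decision values favor class A
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    score <- if (first == pos) dv[, 1] else -dv[, 1]
    list(score = as.numeric(score), label = factor(pr, levels = model$levels))
  } else {
    pr <- predict(model$fit, data = x, num.threads = 1)$predictions
    score <- pr[, pos]
    lab <- ifelse(score > 0.5, pos, neg)
    list(score = as.numeric(score), label = factor(lab, levels = model$levels))
  }
}

#' Predict class labels from a fitted model
#'
#' @param object An `ecs_model` from [grid_search_train()].
#' @param newdata Standardized feature matrix.
#' @param type `"class"` for labels or `"score"` for positive-class scores.
#' @param ... Unused.
#' @return Factor of labels or numeric score vector.
#' @export
predict.ecs_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  ps <- .predict_scores(object, newdata)
  if (type == "class") ps$label else ps$score
}

# Stratified fold assignment.
.make_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (l in levels(factor(y))) {
      ids <- sample(which(y == l))
      f[ids] <- rep_len(seq_len(folds), length(ids))
    }
    f
  })
}

#' Grid-search training with k-fold cross-validation
#'
#' Exhaustive search over a hyperparameter grid using stratified k-fold
#' cross-validation with accuracy as the selection score; the best
#' combination (ties broken by grid order) is refit on the full training
#' set.
#'
#' @param model_type `"knn"`, `"svm"` or `"random_forest"`.
#' @param x_train Standardized training matrix.
#' @param y_train Training labels (factor with 2 levels).
#' @param grid Hyperparameter data.frame; default [default_grid()] or, with
#'   `reduced = TRUE`, [reduced_grid()].
#' @param folds Number of CV folds (default 5).
#' @param reduced Use the reduced grid when `grid` is not supplied.
#' @param positive Positive class label (default `"post_caffeine"`, or the
#'   second factor level when that label is absent).
#' @param seed Seed controlling fold assignment and stochastic learners.
#' @return An `ecs_model` with elements `best_params` and `cv` (the grid
#'   with a `cv_accuracy` column).
#' @export
grid_search_train <- function(model_type, x_train, y_train, grid = NULL,
                              folds = 5, reduced = FALSE,
                              positive = NULL, seed = 1) {
  model_type <- match.arg(model_type, c("knn", "svm", "random_forest"))
  y_train <- factor(y_train)
  if (is.null(grid))
    grid <- if (reduced) reduced_grid(model_type) else default_grid(model_type)
  if (nrow(grid) == 0) stop("grid_search_train: empty grid")
  if (is.null(positive))
    positive <- if ("post_caffeine" %in% levels(y_train)) "post_caffeine"
                else levels(y_train)[2]
  fold_id <- .make_folds(y_train, folds, seed)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (fo in seq_len(folds)) {
      tr <- fold_id != fo
      m <- .fit_one(model_type, grid[gi, , drop = FALSE],
                    x_train[tr, , drop = FALSE], y_train[tr],
                    positive, seed = seed)
      pred <- .predict_scores(m, x_train[!tr, , drop = FALSE])$label
      correct <- correct + sum(pred == y_train[!tr])
    }
    acc[gi] <- correct / length(y_train)
  }
  best <- which.max(acc)
  model <- .fit_one(model_type, grid[best, , drop = FALSE],
                    x_train, y_train, positive, seed = seed)
  model$best_params <- as.list(grid[best, , drop = FALSE])
  model$cv <- cbind(grid, cv_accuracy = acc)
  model
}

#' Evaluate a fitted model on a test set
#'
#' Computes the full metrics bundle for a two-class problem: accuracy,
#' recall and F1 for the positive (post-intervention) class, the ROC curve
#' with trapezoid AUC, the PR curve, the confusion matrix and, when
#' training data are supplied, a learning curve of test accuracy versus
#' training-subset size.
#'
#' @param model An `ecs_model`.
#' @param x_test,y_test Standardized test matrix and labels (both classes
#'   must be present).
#' @param x_train,y_train Optional training data for the learning curve.
#' @param curve_sizes Training fractions for the learning curve.
#' @param seed Seed for learning-curve subsampling.
#' @return An object of class `classifier_report`: list with `accuracy`,
#'   `recall`, `precision`, `f1`, `auc`, `roc_points`, `pr_points`,
#'   `confusion` (rows = truth, columns = prediction), `learning_curve`,
#'   `best_params`.
#' @export
evaluate <- function(model, x_test, y_test, x_train = NULL, y_train = NULL,
                     curve_sizes = c(0.2, 0.4, 0.6, 0.8, 1.0), seed = 1) {
  stopifnot(inherits(model, "ecs_model"))
  y_test <- factor(y_test, levels = model$levels)
  if (nlevels(droplevels(y_test)) < 2)
    stop("evaluate: single-class test set; AUC undefined")
  ps <- .predict_scores(model, x_test)
  pos <- model$positive
  truth_pos <- y_test == pos
  pred_pos <- ps$label == pos
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  confusion <- matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(truth = c(pos, paste0("not_", pos)),
                                      predicted = c(pos, paste0("not_", pos))))
  accuracy <- (tp + tn) / length(y_test)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.finite(recall) && is.finite(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  roc <- roc_points(ps$score, truth_pos)
  auc <- trapezoid_auc(roc$fpr, roc$tpr)
  pr <- pr_points(ps$score, truth_pos)
  lc <- NULL
  if (!is.null(x_train)) {
    y_train <- factor(y_train, levels = model$levels)
    lc <- with_seed(seed, {
      do.call(rbind, lapply(curve_sizes, function(fr) {
        idx <- unlist(lapply(model$levels, function(l) {
          ids <- which(y_train == l)
          sample(ids, max(2L, round(length(ids) * fr)))
        }))
        m <- .fit_one(model$type, as.data.frame(model$best_params),
                      x_train[idx, , drop = FALSE], y_train[idx],
                      pos, seed = seed)
        acc <- mean(.predict_scores(m, x_test)$label == y_test)
        data.frame(train_size = length(idx), test_accuracy = acc)
      }))
    })
  }
  structure(list(accuracy = accuracy, recall = recall, precision = precision,
                 f1 = f1, auc = auc, roc_points = roc, pr_points = pr,
                 confusion = confusion, learning_curve = lc,
                 best_params = model$best_params),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> accuracy %.4f | recall %.4f | ",
                     "F1 %.4f | AUC %.4f\n"),
              x$accuracy, x$recall, x$f1, x$auc))
  invisible(x)
}

#' ROC curve points
#'
#' True/false positive rates swept over all score thresholds (descending),
#' with the (0,0) and (1,1) endpoints included.
#'
#' @param score Numeric scores, higher = more positive.
#' @param truth Logical vector, TRUE for the positive class.
#' @return data.frame with `fpr` and `tpr`.
#' @export
roc_points <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tpr <- cumsum(truth) / max(sum(truth), 1)
  fpr <- cumsum(!truth) / max(sum(!truth), 1)
  # collapse tied scores: keep the last point of each tie group
  s <- score[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' @rdname roc_points
#' @return For `pr_points`: data.frame with `recall` and `precision`.
#' @export
pr_points <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tp <- cumsum(truth)
  prec <- tp / seq_along(truth)
  rec <- tp / max(sum(truth), 1)
  s <- score[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(recall = rec[keep], precision = prec[keep])
}

#' Trapezoid area under a curve
#'
#' @param x,y Curve coordinates (x need not be sorted; sorted internally).
#' @return Numeric area.
#' @export
trapezoid_auc <- function(x, y) {
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
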