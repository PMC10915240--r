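# Small labelled feature matrix with the package's naming scheme: a few
# informative columns plus pure-noise columns.
make_planted <- function(n = 400, n_noise = 200, seed = 21) {
  set.seed(seed)
  y <- factor(rep(c("baseline", "post_caffeine"), length.out = n))
  informative <- sapply(1:5, function(i)
    ifelse(y == "post_caffeine", 1.5, -1.5) + rnorm(n))
  noise <- matrix(rnorm(n * n_noise), n)
  x <- cbind(informative, noise)
  colnames(x) <- c(sprintf("hog_%04d", 1:5),
                   sprintf("lbp_%05d", seq_len(n_noise)))
  list(x = x, y = y)
}

test_that("importance selection filters by threshold and keeps GLCM", {
  d <- make_planted(n = 120, n_noise = 30)
  glcm_block <- matrix(rnorm(120 * 16), 120,
                       dimnames = list(NULL, feature_names("glcm")))
  x <- cbind(d$x, glcm_block)

  all_kept <- importance_selection(x, d$y, threshold = 0, seed = 1)
  expect_setequal(all_kept$kept_names, colnames(x))

  only_glcm <- importance_selection(x, d$y, threshold = 1.1, seed = 1)
  expect_setequal(only_glcm$kept_names, feature_names("glcm"))
  expect_length(only_glcm$kept_names, 16)

  expect_error(importance_selection(x, rep("a", 120)), "2 classes")
})

test_that("selection recovers planted signal dimensions", {
  d <- make_planted()
  sel <- importance_selection(d$x, d$y, threshold = 0.005, seed = 5)
  informative <- sprintf("hog_%04d", 1:5)
  expect_true(all(informative %in% sel$kept_names))
  noise_kept <- setdiff(sel$kept_names, informative)
  expect_lte(length(noise_kept), 0.05 * 200)
  # importances normalized over scored features
  expect_equal(sum(sel$importances), 1, tolerance = 1e-9)
})

test_that("raising the threshold never enlarges the kept set", {
  d <- make_planted(n = 200, n_noise = 50)
  kept_sets <- lapply(c(0, 0.002, 0.005, 0.02, 0.1),
                      function(th) importance_selection(d$x, d$y, threshold = th,
                                                        seed = 3)$kept_names)
  for (i in seq_len(length(kept_sets) - 1))
    expect_true(all(kept_sets[[i + 1]] %in% kept_sets[[i]]))
})

test_that("stratified split and standardization follow their contracts", {
  d <- make_planted(n = 100, n_noise = 10)
  sp <- split_and_standardize(d$x, d$y, seed = 2)
  expect_identical(nrow(sp$x_train), 80L)
  expect_identical(nrow(sp$x_test), 20L)
  expect_identical(as.vector(table(sp$y_test)), c(10L, 10L))

  expect_true(all(abs(colMeans(sp$x_train)) < 1e-9))
  expect_true(all(abs(apply(sp$x_train, 2, sd) - 1) < 1e-9))

  sp2 <- split_and_standardize(d$x, d$y, seed = 2)
  expect_identical(sp$test_idx, sp2$test_idx)

  expect_error(split_and_standardize(d$x[1:3, ], factor(c("a", "b", "b"))),
               "at least 2")
})

test_that("grids have the documented reference cardinalities", {
  expect_identical(nrow(default_grid("knn")), 56L)            # 28 x 2
  expect_identical(nrow(default_grid("svm")), 20402L)         # 101 x 101 x 2
  expect_identical(nrow(default_grid("random_forest")), 8512L) # 152x2x7x4
  expect_identical(range(default_grid("knn")$n_neighbors), c(3L, 30L))
  expect_equal(range(default_grid("svm")$C), c(0.01, 5.01))
  expect_equal(range(default_grid("svm")$gamma), c(0.01, 10.01))
  expect_identical(range(default_grid("random_forest")$n_estimators),
                   c(50L, 201L))
  expect_error(grid_search_train("knn", matrix(0, 4, 2), factor(c(1, 1, 2, 2)),
                                 grid = data.frame()), "empty grid")
})

test_that("all model types separate linearly separable 2-D data", {
  set.seed(13)
  n <- 60
  y <- factor(rep(c("baseline", "post_caffeine"), each = n / 2))
  x <- cbind(a = ifelse(y == "post_caffeine", 3, -3) + rnorm(n, 0, 0.3),
             b = rnorm(n))
  for (mt in c("knn", "svm", "random_forest")) {
    m <- grid_search_train(mt, x, y, reduced = TRUE, seed = 1)
    expect_equal(max(m$cv$cv_accuracy), 1.0)
    expect_true(all(predict(m, x) == y))
  }
})

test_that("uniform-vote KNN route agrees with a reference implementation", {
  skip_if_not_installed("class")
  set.seed(17)
  xtr <- matrix(rnorm(80), 40, 2)
  ytr <- factor(ifelse(xtr[, 1] + 0.2 * rnorm(40) > 0,
                       "post_caffeine", "baseline"))
  xte <- matrix(rnorm(30), 15, 2)
  m <- ecscbf:::.fit_one("knn", list(n_neighbors = 5, weights = "uniform"),
                         xtr, ytr, positive = "post_caffeine")
  ours <- ecscbf:::.predict_scores(m, xte)$label
  ref <- class::knn(xtr, xte, ytr, k = 5)
  agree <- mean(as.character(ours) == as.character(ref))
  expect_gte(agree, 14 / 15)   # reference breaks exact vote ties at random
})

test_that("evaluation metrics match hand arithmetic on a crafted test set", {
  # 1-NN model with train points at known locations so predictions are
  # forced: confusion TP=9, FP=1, FN=2, TN=8
  xtr <- matrix(c(1, -1), 2, 1)
  ytr <- factor(c("post_caffeine", "baseline"))
  m <- ecscbf:::.fit_one("knn", list(n_neighbors = 1, weights = "uniform"),
                         xtr, ytr, positive = "post_caffeine")
  x_test <- matrix(c(rep(1, 9), rep(-1, 2),    # truth positive
                     rep(1, 1), rep(-1, 8)),   # truth negative
                   ncol = 1)
  y_test <- factor(c(rep("post_caffeine", 11), rep("baseline", 9)),
                   levels = c("post_caffeine", "baseline"))
  rep <- evaluate(m, x_test, y_test)
  expect_equal(rep$confusion["post_caffeine", "post_caffeine"], 9)
  expect_equal(rep$confusion["not_post_caffeine", "post_caffeine"], 1)
  expect_equal(rep$confusion["post_caffeine", "not_post_caffeine"], 2)
  expect_equal(rep$confusion["not_post_caffeine", "not_post_caffeine"], 8)
  expect_equal(rep$accuracy, 17 / 20)
  expect_equal(rep$precision, 0.9)
  expect_equal(rep$recall, 9 / 11)
  expect_equal(rep$f1, 2 * (0.9 * 9 / 11) / (0.9 + 9 / 11))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("perfect and random scorers bracket the AUC scale", {
  # perfect predictions
  set.seed(23)
  truth <- rep(c(TRUE, FALSE), each = 10)
  roc <- roc_points(ifelse(truth, 1, 0) + rnorm(20, 0, 1e-6), truth)
  expect_equal(trapezoid_auc(roc$fpr, roc$tpr), 1.0, tolerance = 1e-9)

  # random scores on balanced labels: AUC ~ 0.5
  set.seed(29)
  truth2 <- rep(c(TRUE, FALSE), 1000)
  score2 <- rnorm(2000)
  roc2 <- roc_points(score2, truth2)
  auc2 <- trapezoid_auc(roc2$fpr, roc2$tpr)
  expect_equal(auc2, 0.5, tolerance = 0.05)

  # AUC invariant under strictly monotone score transforms
  roc3 <- roc_points(exp(score2 / 2), truth2)
  expect_equal(trapezoid_auc(roc3$fpr, roc3$tpr), auc2, tolerance = 1e-12)
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- rep(c(TRUE, FALSE), each = 50)
  score <- rnorm(100) + truth
  roc <- roc_points(score, truth)
  ours <- trapezoid_auc(roc$fpr, roc$tpr)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("evaluate rejects a single-class test set", {
  xtr <- matrix(rnorm(20), 10, 2)
  ytr <- factor(rep(c("baseline", "post_caffeine"), 5))
  m <- ecscbf:::.fit_one("knn", list(n_neighbors = 3, weights = "uniform"),
                         xtr, ytr, positive = "post_caffeine")
  expect_error(evaluate(m, xtr[1:4, ], factor(rep("baseline", 4),
                                              levels = levels(ytr))),
               "single-class")
})
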