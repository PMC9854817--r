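test_that("1-NN returns the label of an exactly matching training spectrum", {
  s <- preprocess_set(small_set(seed = 41))
  fit <- fit_knn(s, k_grid = 1, n_folds = 2)
  pred <- predict(fit$model, s)
  expect_identical(as.character(pred), as.character(s$labels))
})

test_that("k = n_train predicts the training majority class everywhere", {
  X <- rbind(matrix(stats::runif(5 * 16), 5, 16),
             matrix(1 + stats::runif(3 * 16), 3, 16))
  s <- toy_set(X, rep(c("HC", "BC"), c(5, 3)))
  m <- ramandx:::fit_family_fixed(s, "knn", list(k = 8))
  pred <- predict(m, s)
  expect_true(all(pred == "HC"))
  prob <- predict(m, s, type = "prob")
  expect_equal(unname(prob[, "HC"]), rep(5 / 8, 8))
})

test_that("CV-selected k matches a brute-force oracle on the same folds", {
  set.seed(55)
  X <- rbind(matrix(stats::rnorm(10 * 12), 10, 12),
             matrix(stats::rnorm(10 * 12, mean = 1.2), 10, 12))
  y <- factor(rep(c("HC", "BC"), each = 10), levels = c("HC", "BC"))
  s <- toy_set(X, as.character(y), class_order = c("HC", "BC"))
  k_grid <- c(1, 3, 5, 7)
  fit <- fit_knn(s, k_grid = k_grid, n_folds = 5, seed = 8)
  # oracle: same fold assignment, naive per-query vote counting
  fold <- ramandx:::make_folds(y, 5, seed = 8)
  oracle_acc <- sapply(k_grid, function(k) {
    accs <- sapply(1:5, function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      pred <- sapply(te, function(i) {
        d <- colSums((t(X[tr, , drop = FALSE]) - X[i, ])^2)
        nn <- tr[order(d)[seq_len(k)]]
        v <- table(factor(as.character(y[nn]), levels = levels(y)))
        levels(y)[which.max(v)]
      })
      mean(pred == as.character(y[te]))
    })
    mean(accs)
  })
  expect_identical(fit$cv$best_params$k,
                   as.integer(k_grid[which.max(oracle_acc)]))
  expect_equal(unname(rowMeans(fit$cv$fold_scores)), unname(oracle_acc))
})

test_that("KNN agrees with the classical reference implementation", {
  skip_if_not_installed("class")
  set.seed(60)
  Xtr <- matrix(stats::rnorm(30 * 10), 30, 10)
  ytr <- factor(rep(c("HC", "BC", "DCIS"), each = 10),
                levels = c("HC", "BC", "DCIS"))
  Xte <- matrix(stats::rnorm(12 * 10), 12, 10)
  ours <- ramandx:::knn_vote(Xtr, ytr, Xte, k = 3,
                             classes = levels(ytr))$class
  ref <- class::knn(Xtr, Xte, ytr, k = 3)
  # compare only queries with an unambiguous 3-vote majority (class::knn
  # breaks ties at random, ours deterministically)
  prob <- ramandx:::knn_vote(Xtr, ytr, Xte, k = 3, classes = levels(ytr))$prob
  clear <- apply(prob, 1, max) > 1 / 3 + 1e-9
  expect_identical(as.character(ours[clear]), as.character(ref[clear]))
})

test_that("a deep single tree interpolates well-separated training data", {
  set.seed(62)
  X <- rbind(matrix(stats::rnorm(10 * 16, 0, 0.1), 10, 16),
             matrix(stats::rnorm(10 * 16, 3, 0.1), 10, 16))
  s <- toy_set(X, rep(c("HC", "BC"), each = 10))
  m <- ramandx:::fit_family_fixed(s, "rf", list(n_trees = 1, depth = Inf),
                                  seed = 5)
  expect_identical(as.character(predict(m, s)), as.character(s$labels))
})

test_that("random-forest fitting is seed-reproducible and CV-tuned", {
  s <- preprocess_set(small_set(seed = 43))
  f1 <- fit_rf(s, n_trees_grid = c(50, 100), depth_grid = c(5, Inf),
               n_folds = 3, seed = 7)
  f2 <- fit_rf(s, n_trees_grid = c(50, 100), depth_grid = c(5, Inf),
               n_folds = 3, seed = 7)
  expect_identical(predict(f1$model, s), predict(f2$model, s))
  expect_equal(f1$cv$best_cv_accuracy,
               max(rowMeans(f1$cv$fold_scores)))
  expect_gte(f1$cv$best_cv_accuracy, 0.9)  # separable synthetic classes
})

test_that("the RBF SVM separates distinct constant-profile classes", {
  X <- rbind(matrix(rep(seq(0, 1, length.out = 16), each = 8), 8, 16),
             matrix(rep(seq(1, 0, length.out = 16), each = 8), 8, 16))
  X <- X + matrix(stats::rnorm(length(X), 0, 0.01), nrow(X))
  s <- toy_set(X, rep(c("HC", "BC"), each = 8))
  m <- ramandx:::fit_family_fixed(s, "svm", list(cost = 10, gamma = 0.1),
                                  seed = 3)
  expect_identical(as.character(predict(m, s)), as.character(s$labels))
})

test_that("the RBF kernel handles an XOR arrangement better than chance", {
  set.seed(65)
  proto <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  lab <- c("HC", "BC", "BC", "HC")
  X <- proto[rep(1:4, each = 6), ]
  X <- cbind(X, X, X, X)  # length-8 "spectra"
  X <- X + matrix(stats::rnorm(length(X), 0, 0.05), nrow(X))
  s <- toy_set(X, rep(lab, each = 6))
  m <- ramandx:::fit_family_fixed(s, "svm", list(cost = 10, gamma = 1),
                                  seed = 4)
  acc <- mean(predict(m, s) == s$labels)
  expect_gt(acc, 0.5)
})

test_that("SVM grid search selects the accuracy-maximizing combination", {
  s <- preprocess_set(small_set(seed = 44))
  fit <- fit_svm(s, c_grid = c(1, 10), gamma_grid = c(0.01, 0.1),
                 n_folds = 3, seed = 2)
  cv <- fit$cv
  expect_equal(cv$best_cv_accuracy, max(rowMeans(cv$fold_scores)))
  expect_identical(cv$best_index, which.max(rowMeans(cv$fold_scores)))
  expect_identical(cv$best_params, cv$grid[[cv$best_index]])
})

test_that("probability rows sum to one for every family", {
  s <- preprocess_set(small_set(seed = 45))
  test <- s[seq(1, length(s), by = 3)]
  models <- list(
    ramandx:::fit_family_fixed(s, "knn", list(k = 3)),
    ramandx:::fit_family_fixed(s, "rf", list(n_trees = 50, depth = Inf),
                               seed = 1),
    ramandx:::fit_family_fixed(s, "svm", list(cost = 10, gamma = 0.05),
                               seed = 1),
    ramandx:::fit_family_fixed(s, "cnn",
                               list(spec = cnn_spec(input_len = 96,
                                                    epochs = 2,
                                                    conv_channels = c(4, 6)),
                                    val_fraction = 0), seed = 1))
  for (m in models) {
    p <- predict(m, test, type = "prob")
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
    expect_identical(colnames(p), m$classes)
  }
})

test_that("raman_train dispatches families and validates grids", {
  s <- preprocess_set(small_set(seed = 46))
  m <- raman_train(s, "knn", k_grid = c(1, 3), n_folds = 2)
  expect_s3_class(m, "raman_model")
  expect_identical(m$family, "KNN")
  expect_error(fit_knn(s, k_grid = integer(0)), "empty")
  expect_error(fit_rf(s, n_trees_grid = numeric(0)), "empty")
  expect_error(fit_svm(s, c_grid = -1, gamma_grid = 1), "positive")
})
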