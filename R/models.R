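# Stratified fold assignment used by every grid search.
make_folds <- function(labels, k = 5, seed = 1) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated grid search
#'
#' Evaluates each hyperparameter combination by stratified k-fold
#' cross-validation and selects the one with the highest mean fold accuracy
#' (ties broken by grid order).
#'
#' @param X Feature matrix (spectra as rows).
#' @param y Factor of class labels.
#' @param grid List of hyperparameter combinations (each a named list).
#' @param fit_predict Function \code{(Xtr, ytr, Xte, params)} returning the
#'   predicted class labels for \code{Xte}.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class \code{cv_result}: the grid, the
#'   per-combination per-fold accuracies, the selected combination and its
#'   mean cross-validation accuracy.
#' @export
cross_validate <- function(X, y, grid, fit_predict, n_folds = 5, seed = 1) {
  if (!length(grid)) stop("empty hyperparameter grid")
  fold <- make_folds(y, n_folds, seed)
  scores <- matrix(NA_real_, length(grid), n_folds)
  for (g in seq_along(grid)) {
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      pred <- fit_predict(X[tr, , drop = FALSE], droplevels(y[tr]),
                          X[!tr, , drop = FALSE], grid[[g]])
      scores[g, f] <- mean(as.character(pred) == as.character(y[!tr]))
    }
  }
  mean_acc <- rowMeans(scores)
  best <- which.max(mean_acc)
  structure(list(grid = grid, fold_scores = scores, best_index = best,
                 best_params = grid[[best]],
                 best_cv_accuracy = mean_acc[best]),
            class = "cv_result")
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d combination(s) x %d folds; best CV accuracy %.4f\n",
              length(x$grid), ncol(x$fold_scores), x$best_cv_accuracy))
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- KNN ------------------------------------------------------------------

knn_vote <- function(Xtr, ytr, Xte, k, classes) {
  d2 <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
  prob <- matrix(0, nrow(Xte), length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(d2[i, ])[seq_len(k)]          # stable: distance then index
    v <- table(factor(as.character(ytr[nn]), levels = classes))
    prob[i, ] <- as.numeric(v) / k
  }
  cls <- classes[max.col(prob, ties.method = "first")]  # tie: lowest index
  list(class = factor(cls, levels = classes), prob = prob)
}

#' Fit a k-nearest-neighbour classifier
#'
#' Selects k by stratified 5-fold cross-validation over \code{k_grid}, then
#' stores the training spectra for majority-vote prediction by Euclidean
#' distance. Class ties break toward the lowest class index; per-class vote
#' fractions serve as probability scores for ROC analysis.
#'
#' @param train_set Labelled \code{\link{spectrum_set}}.
#' @param k_grid Candidate neighbourhood sizes.
#' @param n_folds CV folds.
#' @param seed Fold-assignment seed.
#' @return List with \code{model} (class \code{c("raman_knn","raman_model")})
#'   and \code{cv} (a \code{\link{cross_validate}} result).
#' @export
fit_knn <- function(train_set, k_grid = seq(1, 15, by = 2), n_folds = 5,
                    seed = 1) {
  stopifnot(inherits(train_set, "spectrum_set"))
  if (is.null(train_set$labels)) stop("training set must be labelled")
  if (!length(k_grid)) stop("empty k grid")
  y <- droplevels(train_set$labels)
  X <- train_set$intensities
  if (any(k_grid < 1) || any(k_grid >= nrow(X)))
    stop("k values must be >= 1 and < n_train")
  classes <- levels(y)
  grid <- lapply(k_grid, function(k) list(k = as.integer(k)))
  cv <- cross_validate(X, y, grid, function(Xtr, ytr, Xte, p)
    knn_vote(Xtr, ytr, Xte, min(p$k, nrow(Xtr)), levels(ytr))$class,
    n_folds, seed)
  model <- structure(list(family = "KNN", X = X, y = y, k = cv$best_params$k,
                          classes = classes, cv = cv),
                     class = c("raman_knn", "raman_model"))
  list(model = model, cv = cv)
}

# ---- Random forest --------------------------------------------------------

rf_fit_one <- function(Xtr, ytr, params, seed) {
  maxnodes <- if (is.finite(params$depth))
    min(2^params$depth, nrow(Xtr)) else NULL
  set.seed(seed)
  randomForest::randomForest(x = Xtr, y = ytr, ntree = params$n_trees,
                             maxnodes = maxnodes)
}

#' Fit a random-forest classifier
#'
#' Bagged decision trees with majority voting. The number of trees and the
#' tree depth are tuned by stratified 5-fold cross-validation; depth d is
#' enforced as a cap of 2^d terminal nodes (unlimited when infinite).
#'
#' @param train_set Labelled \code{\link{spectrum_set}}.
#' @param n_trees_grid Candidate forest sizes.
#' @param depth_grid Candidate depths (use \code{Inf} for unlimited).
#' @param n_folds CV folds.
#' @param seed Seed for folds and tree growing.
#' @return List with \code{model} (class \code{c("raman_rf","raman_model")})
#'   and \code{cv}.
#' @export
fit_rf <- function(train_set, n_trees_grid = c(100, 200, 500),
                   depth_grid = c(5, 10, Inf), n_folds = 5, seed = 1) {
  stopifnot(inherits(train_set, "spectrum_set"))
  if (is.null(train_set$labels)) stop("training set must be labelled")
  if (!length(n_trees_grid) || !length(depth_grid)) stop("empty grid")
  y <- droplevels(train_set$labels)
  X <- train_set$intensities
  grid <- list()
  for (nt in n_trees_grid) for (d in depth_grid)
    grid[[length(grid) + 1L]] <- list(n_trees = as.integer(nt), depth = d)
  cv <- cross_validate(X, y, grid, function(Xtr, ytr, Xte, p)
    stats::predict(rf_fit_one(Xtr, ytr, p, seed), Xte), n_folds, seed)
  fit <- rf_fit_one(X, y, cv$best_params, seed)
  model <- structure(list(family = "RF", fit = fit, classes = levels(y),
                          cv = cv),
                     class = c("raman_rf", "raman_model"))
  list(model = model, cv = cv)
}

# ---- SVM (RBF, one-vs-rest) ----------------------------------------------

svm_ovr_fit <- function(X, y, cost, gamma, seed) {
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    ybin <- factor(ifelse(as.character(y) == cl, "pos", "rest"),
                   levels = c("rest", "pos"))
    set.seed(seed)  # Platt probability calibration shuffles internally
    e1071::svm(x = X, y = ybin, kernel = "radial", cost = cost,
               gamma = gamma, probability = TRUE, scale = FALSE)
  })
  names(fits) <- classes
  fits
}

svm_ovr_scores <- function(fits, X) {
  s <- sapply(fits, function(f) {
    p <- stats::predict(f, X, probability = TRUE)
    attr(p, "probabilities")[, "pos"]
  })
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list(NULL, names(fits)))
  s / rowSums(s)
}

#' Fit an RBF-kernel support vector machine
#'
#' Maximum-margin classification with a radial basis function kernel,
#' decomposed one-vs-rest for multiclass problems. The cost C and kernel
#' width gamma are selected by grid search under stratified 5-fold
#' cross-validation. Per-class probability scores (Platt-calibrated within
#' each binary machine, normalized across classes) are available for ROC
#' analysis.
#'
#' @param train_set Labelled \code{\link{spectrum_set}}.
#' @param c_grid Candidate cost values (> 0).
#' @param gamma_grid Candidate kernel widths (> 0).
#' @param n_folds CV folds.
#' @param seed Seed for folds and probability calibration.
#' @return List with \code{model} (class \code{c("raman_svm","raman_model")})
#'   and \code{cv}.
#' @export
fit_svm <- function(train_set, c_grid = c(0.1, 1, 10, 100),
                    gamma_grid = 10^seq(-4, 0), n_folds = 5, seed = 1) {
  stopifnot(inherits(train_set, "spectrum_set"))
  if (is.null(train_set$labels)) stop("training set must be labelled")
  if (!length(c_grid) || !length(gamma_grid)) stop("empty grid")
  if (any(c_grid <= 0) || any(gamma_grid <= 0))
    stop("C and gamma must be positive")
  y <- droplevels(train_set$labels)
  X <- train_set$intensities
  grid <- list()
  for (cc in c_grid) for (g in gamma_grid)
    grid[[length(grid) + 1L]] <- list(cost = cc, gamma = g)
  cv <- cross_validate(X, y, grid, function(Xtr, ytr, Xte, p) {
    fits <- svm_ovr_fit(Xtr, ytr, p$cost, p$gamma, seed)
    sc <- svm_ovr_scores(fits, Xte)
    factor(levels(ytr)[max.col(sc, ties.method = "first")],
           levels = levels(ytr))
  }, n_folds, seed)
  fits <- svm_ovr_fit(X, y, cv$best_params$cost, cv$best_params$gamma, seed)
  model <- structure(list(family = "SVM", fits = fits, classes = levels(y),
                          cv = cv),
                     class = c("raman_svm", "raman_model"))
  list(model = model, cv = cv)
}

# ---- Unified modelling interface -----------------------------------------

#' Train a spectral classifier
#'
#' Unified fitting front end over the four families: the 1D CNN (built and
#' trained from a \code{\link{cnn_spec}}) and the KNN, random-forest and
#' RBF-SVM baselines with cross-validated hyperparameter search.
#'
#' @param train_set Preprocessed, labelled \code{\link{spectrum_set}}.
#' @param family One of \code{"cnn"}, \code{"knn"}, \code{"rf"},
#'   \code{"svm"}.
#' @param seed Seed controlling initialization, fold assignment and any
#'   stochastic fitting step.
#' @param spec \code{\link{cnn_spec}} used when \code{family = "cnn"}
#'   (its \code{input_len} and \code{n_classes} are aligned to the data).
#' @param val_fraction Validation holdout fraction for CNN history curves.
#' @param ... Passed to the family's fitting function (grids, fold counts).
#' @return A fitted \code{raman_model}; for the baselines the grid-search
#'   summary is attached as \code{$cv}, for the CNN the per-epoch history as
#'   \code{$history}.
#' @examples
#' cfg <- generator_config(n_per_class = c(HC = 12, BC = 12, DCIS = 8),
#'                         axis_n = 64, seed = 7)
#' d <- preprocess_set(generate_dataset(cfg))
#' m <- raman_train(d, "knn", k_grid = c(1, 3), n_folds = 2)
#' predict(m, d[1:3])
#' @export
raman_train <- function(train_set, family = c("cnn", "knn", "rf", "svm"),
                        seed = 1, spec = NULL, val_fraction = 0.2, ...) {
  family <- match.arg(family)
  switch(family,
    cnn = {
      if (is.null(spec)) spec <- cnn_spec()
      nc <- length(levels(droplevels(train_set$labels)))
      if (spec$input_len != ncol(train_set$intensities) ||
          spec$n_classes != nc) {
        spec <- cnn_spec(input_len = ncol(train_set$intensities),
                         conv_channels = spec$conv_channels,
                         kernel_len = spec$kernel_len,
                         pool_len = spec$pool_len,
                         hidden_activation = spec$hidden_activation,
                         n_classes = nc, batch_size = spec$batch_size,
                         epochs = spec$epochs,
                         learning_rate = spec$learning_rate)
      }
      train_cnn(build_cnn(spec, seed), train_set,
                val_fraction = val_fraction, seed = seed)
    },
    knn = fit_knn(train_set, seed = seed, ...)$model,
    rf = fit_rf(train_set, seed = seed, ...)$model,
    svm = fit_svm(train_set, seed = seed, ...)$model)
}

as_feature_matrix <- function(newdata) {
  if (inherits(newdata, "spectrum_set")) newdata$intensities
  else as.matrix(newdata)
}

#' Predict from a fitted spectral classifier
#'
#' @param object A \code{raman_model}.
#' @param newdata A \code{\link{spectrum_set}} or numeric matrix of spectra
#'   (rows), preprocessed the same way as the training data.
#' @param type \code{"class"} for labels, \code{"prob"} for the per-class
#'   score matrix (rows sum to 1).
#' @param ... Ignored.
#' @return Factor of predicted labels, or an N x K probability matrix.
#' @export
predict.raman_model <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  prob <- switch(object$family,
    CNN = {
      p <- cnn_predict_proba(object, X)
      colnames(p) <- object$classes
      p
    },
    KNN = knn_vote(object$X, object$y, X, object$k, object$classes)$prob,
    RF = {
      p <- stats::predict(object$fit, X, type = "prob")
      p[, object$classes, drop = FALSE]
    },
    SVM = svm_ovr_scores(object$fits, X)[, object$classes, drop = FALSE])
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' @export
#' @method print raman_model
print.raman_model <- function(x, ...) {
  cat(sprintf("<raman_model> family=%s, classes: %s\n", x$family,
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$cv))
    cat(sprintf("  CV accuracy %.4f (%s)\n", x$cv$best_cv_accuracy,
                paste(names(x$cv$best_params), unlist(x$cv$best_params),
                      sep = "=", collapse = ", ")))
  if (x$family == "CNN" && nrow(x$history))
    cat(sprintf("  trained %d epoch(s); final train acc %.4f, val acc %.4f\n",
                nrow(x$history), utils::tail(x$history$train_acc, 1),
                utils::tail(x$history$val_acc, 1)))
  invisible(x)
}

#' @export
#' @method summary raman_model
summary.raman_model <- function(object, ...) {
  print(object)
  if (object$family == "CNN") {
    s <- object$spec
    cat(sprintf("  conv(%d,k=%d) -> batch-norm -> tanh -> conv(%d,k=%d) -> tanh -> maxpool(%d) -> flatten(%d) -> dense(%d) -> softmax\n",
                s$conv_channels[1], s$kernel_len, s$conv_channels[2],
                s$kernel_len, s$pool_len, flattened_size(s), s$n_classes))
    cat(sprintf("  batch %d, epochs %d, lr %g, %s\n", s$batch_size, s$epochs,
                s$learning_rate, s$optimizer))
  }
  invisible(object)
}

#' Plot CNN training history
#'
#' Accuracy and loss curves for the training and validation sets, one panel
#' each, over epochs.
#'
#' @param x A trained \code{raman_cnn} model.
#' @param ... Ignored.
#' @export
plot.raman_cnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "Epoch",
                    ylab = "Accuracy")
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "Epoch",
                    ylab = "Loss")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
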