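#' Stratified train/test split
#'
#' Partitions sample indices so that each class contributes
#' \code{floor(train_frac * n_class)} samples to the training set, chosen
#' uniformly at random; the remainder forms the test set. With class counts
#' (241, 463, 100) and a 0.7 fraction this yields the canonical 168/324/70
#' training and 73/139/30 test cells (562 vs 242 in total).
#'
#' @param labels Factor or character vector of class labels.
#' @param train_frac Training fraction in (0, 1).
#' @param seed RNG seed.
#' @return Object of class \code{split_result}: \code{train_indices},
#'   \code{test_indices} and a per-class count matrix.
#' @examples
#' lab <- rep(c("HC", "BC", "DCIS"), c(241, 463, 100))
#' s <- stratified_split(lab, 0.7, seed = 1)
#' s$per_class_counts
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("'train_frac' must be in (0, 1)")
  lab <- as.character(labels)
  classes <- if (is.factor(labels)) levels(droplevels(labels)) else unique(lab)
  cnt <- table(factor(lab, levels = classes))
  if (any(cnt < 2)) stop("every class needs at least 2 members")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(lab == cl)
    n_tr <- floor(train_frac * length(idx))
    train_idx <- c(train_idx, idx[sample.int(length(idx), n_tr)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(lab), train_idx)
  pc <- sapply(classes, function(cl)
    c(train = sum(lab[train_idx] == cl), test = sum(lab[test_idx] == cl)))
  structure(list(train_indices = train_idx, test_indices = test_idx,
                 per_class_counts = pc),
            class = "split_result")
}

#' @export
#' @method print split_result
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train n=%d, test n=%d\n",
              length(x$train_indices), length(x$test_indices)))
  print(x$per_class_counts)
  invisible(x)
}

#' Confusion matrix
#'
#' Contingency table of true (rows) against predicted (columns) classes.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_order Label vocabulary defining row/column order.
#' @return Object of class \code{confusion_matrix}: an integer K x K matrix
#'   with \code{class_order} dimnames.
#' @export
confusion <- function(y_true, y_pred, class_order = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length")
  if (is.null(class_order)) class_order <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  m <- matrix(as.integer(cm), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
#' @method print confusion_matrix
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy (trace over total), misdiagnosis count (off-diagonal sum) and,
#' for a 2x2 matrix with a declared positive class, sensitivity (recall of
#' the positive class) and specificity (recall of the other class). A class
#' absent from the truth makes its recall undefined; the value is returned
#' as \code{NA} with \code{undefined = TRUE} rather than silently as 0.
#'
#' @param cm A \code{\link{confusion}} matrix.
#' @param positive_class Positive label for the 2x2 case.
#' @return Object of class \code{metrics_report} with \code{accuracy},
#'   \code{misdiagnoses}, and for binary input \code{sensitivity} and
#'   \code{specificity}.
#' @examples
#' cm <- confusion(rep(c("HC", "BC"), c(3, 4)),
#'                 c("HC", "HC", "BC", "BC", "BC", "BC", "HC"),
#'                 c("HC", "BC"))
#' metrics_from_cm(cm, positive_class = "BC")
#' @export
metrics_from_cm <- function(cm, positive_class = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  total <- sum(m)
  acc <- sum(diag(m)) / total
  out <- list(accuracy = acc, misdiagnoses = as.integer(total - sum(diag(m))),
              undefined = FALSE)
  if (!is.null(positive_class)) {
    if (nrow(m) != 2)
      stop("sensitivity/specificity need a 2x2 matrix")
    if (!positive_class %in% rownames(m))
      stop("'positive_class' not in the matrix classes")
    neg <- setdiff(rownames(m), positive_class)
    pos_n <- sum(m[positive_class, ]); neg_n <- sum(m[neg, ])
    out$sensitivity <- if (pos_n == 0) NA_real_ else
      m[positive_class, positive_class] / pos_n
    out$specificity <- if (neg_n == 0) NA_real_ else m[neg, neg] / neg_n
    out$positive_class <- positive_class
    out$undefined <- pos_n == 0 || neg_n == 0
  }
  structure(out, class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, %d misdiagnose(s)", 100 * x$accuracy,
              x$misdiagnoses))
  if (!is.null(x$sensitivity))
    cat(sprintf("; sensitivity %.2f%%, specificity %.2f%% (positive = %s)",
                100 * x$sensitivity, 100 * x$specificity, x$positive_class))
  cat("\n")
  invisible(x)
}

# Binary ROC curve by threshold sweep over the positive-class score;
# trapezoidal AUC (ties share a single threshold, so tied pairs earn half
# credit, matching the Mann-Whitney statistic).
binary_roc <- function(score, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) stop("ROC needs both classes present")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- is_pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' ROC curves and AUC
#'
#' For two classes: the standard ROC over the positive-class score ranking,
#' integrated by the trapezoidal rule. For three or more classes: one
#' one-vs-rest curve per class, with the macro-averaged AUC as the summary.
#'
#' @param scores N x K matrix of class scores (columns named by class), or a
#'   vector of positive-class scores for the binary scheme.
#' @param y_true True labels.
#' @param scheme \code{"macro_ovr"} or \code{"binary"}.
#' @param positive_class Positive label for the binary scheme.
#' @return List with \code{auc}, \code{per_class_auc} (macro scheme) and
#'   \code{roc_points} (data frames of FPR/TPR).
#' @export
roc_auc <- function(scores, y_true, scheme = c("macro_ovr", "binary"),
                    positive_class = NULL) {
  scheme <- match.arg(scheme)
  y <- as.character(y_true)
  if (length(unique(y)) < 2) stop("'y_true' contains a single class")
  if (scheme == "binary") {
    if (is.matrix(scores)) {
      if (is.null(positive_class)) stop("binary scheme needs 'positive_class'")
      scores <- scores[, positive_class]
    }
    r <- binary_roc(scores, y == positive_class)
    return(list(auc = r$auc,
                roc_points = list(data.frame(fpr = r$fpr, tpr = r$tpr))))
  }
  if (!is.matrix(scores) || is.null(colnames(scores)))
    stop("macro scheme needs a score matrix with class column names")
  if (nrow(scores) != length(y)) stop("scores rows must align with y_true")
  classes <- colnames(scores)
  per <- numeric(length(classes)); names(per) <- classes
  pts <- vector("list", length(classes)); names(pts) <- classes
  for (cl in classes) {
    r <- binary_roc(scores[, cl], y == cl)
    per[cl] <- r$auc
    pts[[cl]] <- data.frame(fpr = r$fpr, tpr = r$tpr)
  }
  list(auc = mean(per), per_class_auc = per, roc_points = pts)
}

# Fit one family with fixed hyperparameters (no grid search); used for the
# pairwise binary experiments, which reuse the hyperparameters selected in
# the three-class run.
fit_family_fixed <- function(train_set, family, params = list(), seed = 1) {
  switch(family,
    knn = {
      y <- droplevels(train_set$labels)
      k <- if (!is.null(params$k)) params$k else 5L
      structure(list(family = "KNN", X = train_set$intensities, y = y,
                     k = as.integer(k), classes = levels(y), cv = NULL),
                class = c("raman_knn", "raman_model"))
    },
    rf = {
      y <- droplevels(train_set$labels)
      p <- list(n_trees = if (!is.null(params$n_trees)) params$n_trees else 500L,
                depth = if (!is.null(params$depth)) params$depth else Inf)
      structure(list(family = "RF",
                     fit = rf_fit_one(train_set$intensities, y, p, seed),
                     classes = levels(y), cv = NULL),
                class = c("raman_rf", "raman_model"))
    },
    svm = {
      y <- droplevels(train_set$labels)
      cost <- if (!is.null(params$cost)) params$cost else 10
      gamma <- if (!is.null(params$gamma)) params$gamma else 0.01
      structure(list(family = "SVM",
                     fits = svm_ovr_fit(train_set$intensities, y, cost, gamma,
                                        seed),
                     classes = levels(y), cv = NULL),
                class = c("raman_svm", "raman_model"))
    },
    cnn = {
      spec0 <- if (!is.null(params$spec)) params$spec else cnn_spec()
      raman_train(train_set, "cnn", seed = seed, spec = spec0,
                  val_fraction = if (!is.null(params$val_fraction))
                    params$val_fraction else 0.2)
    },
    stop("unknown family: ", family))
}

#' Pairwise binary classification experiments
#'
#' For each class pair (HC/BC, HC/DCIS, BC/DCIS) the three-class train/test
#' partition is restricted to samples of the pair -- the same samples keep
#' the same train or test membership -- each requested family is refitted on
#' the restricted training set, and a 2x2 confusion matrix with sensitivity,
#' specificity, accuracy and AUC is reported. The positive class is the
#' second of the pair (the later-stage condition).
#'
#' @param set Preprocessed, labelled \code{\link{spectrum_set}} (the full
#'   dataset the split indexes into).
#' @param split A \code{\link{stratified_split}} result for \code{set}.
#' @param families Character vector from
#'   \code{c("knn", "rf", "svm", "cnn")}.
#' @param params Named list (per family) of fixed hyperparameters, e.g.
#'   \code{list(knn = list(k = 5), svm = list(cost = 10, gamma = 0.01))}.
#' @param seed Seed for the stochastic fitters.
#' @return Nested list: one element per pair (named \code{"HC_vs_BC"} etc.),
#'   each holding per-family confusion matrices and metric reports.
#' @export
run_binary_experiments <- function(set, split,
                                   families = c("knn", "rf", "svm", "cnn"),
                                   params = list(), seed = 1) {
  stopifnot(inherits(set, "spectrum_set"), inherits(split, "split_result"))
  if (is.null(set$labels)) stop("set must be labelled")
  classes <- levels(droplevels(set$labels))
  if (length(classes) < 3)
    stop("pairwise experiments need at least 3 classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    keep <- as.character(set$labels) %in% pr
    tr_idx <- intersect(split$train_indices, which(keep))
    te_idx <- intersect(split$test_indices, which(keep))
    sub_order <- pr
    restrict <- function(idx) {
      s <- set[idx]
      spectrum_set(s$axis, s$intensities, as.character(s$labels),
                   s$sample_ids, class_order = sub_order)
    }
    train <- restrict(tr_idx)
    test <- restrict(te_idx)
    pos <- pr[2]
    fam_out <- list()
    for (fam in families) {
      model <- fit_family_fixed(train, fam, params[[fam]], seed)
      pred <- predict(model, test)
      prob <- predict(model, test, type = "prob")
      cm <- confusion(test$labels, pred, class_order = pr)
      met <- metrics_from_cm(cm, positive_class = pos)
      roc <- roc_auc(prob[, pos], test$labels, scheme = "binary",
                     positive_class = pos)
      fam_out[[fam]] <- list(confusion = cm, metrics = met, auc = roc$auc,
                             roc_points = roc$roc_points[[1]])
    }
    out[[paste(pr, collapse = "_vs_")]] <-
      list(pair = pr, positive_class = pos, families = fam_out)
  }
  out
}

#' Run the full diagnostic experiment
#'
#' Executes the complete protocol on one configuration: generate (or accept)
#' a dataset, preprocess it, split it 7:3 stratified, tune each classifier
#' family by stratified 5-fold cross-validation, fit the tuned model on the
#' full training set, evaluate three-class performance (confusion matrix,
#' accuracy, macro one-vs-rest AUC), and repeat the pairwise binary
#' experiments on the same partition. Optionally writes a report bundle
#' (\code{report.json}, \code{confusion_*.csv}, \code{roc_*.csv},
#' \code{history.csv}, \code{config.yaml}, \code{run.log}) to a directory.
#'
#' @param config A \code{run_config} from \code{\link{load_config}} or
#'   \code{\link{default_run_config}}.
#' @param data Optional pre-generated \code{\link{spectrum_set}}; when
#'   \code{NULL} the configured generator is used.
#' @param out_dir Optional output directory for the report bundle.
#' @return Object of class \code{raman_report}: a nested list with the
#'   split, per-family CV summaries, three-class and binary results, and the
#'   CNN training history.
#' @export
run_full_experiment <- function(config = default_run_config(), data = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stages <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    stages <<- c(stages, sprintf("%s ok", name))
    res
  }
  raw <- if (is.null(data)) stage("synth", generate_dataset(config$generator))
    else data
  pp <- stage("preprocess", preprocess_set(raw, config$preprocess))
  split <- stage("split", stratified_split(pp$labels,
                                           config$split$train_frac,
                                           config$split$seed))
  train <- pp[split$train_indices]
  test <- pp[split$test_indices]
  families <- config$models$families
  seed <- config$split$seed
  cv_out <- list(); three <- list(); fixed_params <- list()
  history <- NULL
  for (fam in families) {
    res <- stage(paste0("fit_", fam), switch(fam,
      knn = fit_knn(train, k_grid = config$models$knn$k_grid, seed = seed),
      rf = fit_rf(train, n_trees_grid = config$models$rf$n_trees_grid,
                  depth_grid = config$models$rf$depth_grid, seed = seed),
      svm = fit_svm(train, c_grid = config$models$svm$c_grid,
                    gamma_grid = config$models$svm$gamma_grid, seed = seed),
      cnn = {
        spec <- do.call(cnn_spec, c(list(
          input_len = ncol(train$intensities),
          n_classes = length(levels(droplevels(train$labels)))),
          config$models$cnn$spec))
        cv <- if (isTRUE(config$models$cnn$do_cv)) {
          cross_validate(train$intensities, droplevels(train$labels),
                         list(list(spec = spec)),
                         function(Xtr, ytr, Xte, p) {
                           s <- spectrum_set(train$axis, Xtr,
                                             as.character(ytr),
                                             class_order = levels(ytr))
                           m <- raman_train(s, "cnn", seed = seed,
                                            spec = p$spec,
                                            val_fraction = 0)
                           predict(m, Xte)
                         }, n_folds = 5, seed = seed)
        } else NULL
        model <- raman_train(train, "cnn", seed = seed, spec = spec,
                             val_fraction = config$models$cnn$val_fraction)
        model$cv <- cv
        list(model = model, cv = cv)
      }))
    model <- res$model
    cv_out[[fam]] <- res$cv
    fixed_params[[fam]] <- switch(fam,
      knn = list(k = model$k),
      rf = res$cv$best_params,
      svm = res$cv$best_params,
      cnn = list(spec = model$spec,
                 val_fraction = config$models$cnn$val_fraction))
    if (fam == "cnn") history <- model$history
    pred <- predict(model, test)
    prob <- predict(model, test, type = "prob")
    cm <- confusion(test$labels, pred,
                    class_order = levels(droplevels(pp$labels)))
    met <- metrics_from_cm(cm)
    roc <- roc_auc(prob, test$labels, scheme = "macro_ovr")
    three[[fam]] <- list(confusion = cm, metrics = met,
                         auc_macro = roc$auc,
                         per_class_auc = roc$per_class_auc,
                         roc_points = roc$roc_points)
  }
  binary <- stage("binary",
                  run_binary_experiments(pp, split, families,
                                         params = fixed_params, seed = seed))
  report <- structure(list(
    meta = list(seed = seed, families = families,
                n_samples = nrow(pp$intensities),
                config_hash = config_hash(config),
                svm_score_scheme = "Platt-calibrated one-vs-rest, normalized",
                knn_score_scheme = "vote fractions"),
    split = list(train_n = length(split$train_indices),
                 test_n = length(split$test_indices),
                 per_class_counts = split$per_class_counts),
    cv = cv_out, three_class = three, binary = binary,
    history = history), class = "raman_report")
  if (!is.null(out_dir))
    write_report_bundle(report, config, out_dir,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")),
                        stages = stages)
  report
}

#' @export
#' @method print raman_report
print.raman_report <- function(x, ...) {
  cat(sprintf("<raman_report> %d samples, train/test %d/%d\n",
              x$meta$n_samples, x$split$train_n, x$split$test_n))
  for (fam in names(x$three_class)) {
    t3 <- x$three_class[[fam]]
    cat(sprintf("  %-4s three-class accuracy %.2f%%, %d misdiagnoses, macro AUC %.3f\n",
                toupper(fam), 100 * t3$metrics$accuracy,
                t3$metrics$misdiagnoses, t3$auc_macro))
  }
  invisible(x)
}
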