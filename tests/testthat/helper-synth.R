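# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# A quick low-resolution labelled dataset with strong class effects.
small_set <- function(n = c(HC = 12, BC = 14, DCIS = 8), axis_n = 96,
                      noise_sd = 0.01, jitter_sd = 0.03, seed = 101,
                      multipliers = NULL) {
  peaks <- default_peaks()
  if (!is.null(multipliers))
    peaks <- lapply(peaks, function(p) {
      p$class_multipliers <- multipliers
      p
    })
  generate_dataset(generator_config(
    n_per_class = n, peaks = peaks, noise_sd = noise_sd,
    jitter_sd = jitter_sd, replicates = 3, seed = seed, axis_n = axis_n))
}

# Direct matrix-backed set for toy classifier problems.
toy_set <- function(X, labels, class_order = NULL) {
  spectrum_set(make_axis(0, 100, ncol(X)), X, labels,
               class_order = class_order)
}

# The confusion matrices printed for the three-class test-set comparison of
# the four algorithms (rows = true HC, BC, DCIS).
printed_cm3 <- function() {
  list(
    knn = matrix(c(47, 24, 2, 9, 127, 3, 2, 11, 17), 3, byrow = TRUE),
    rf  = matrix(c(43, 30, 0, 5, 134, 0, 1, 10, 19), 3, byrow = TRUE),
    svm = matrix(c(67, 6, 0, 7, 132, 0, 0, 0, 30), 3, byrow = TRUE),
    cnn = matrix(c(72, 1, 0, 2, 137, 0, 0, 0, 30), 3, byrow = TRUE))
}

# The printed binary confusion matrices: pair -> algorithm -> 2x2 (rows =
# true first/second class of the pair; positive class is the second).
printed_cm2 <- function() {
  list(
    HC_BC = list(
      knn = matrix(c(53, 20, 16, 123), 2, byrow = TRUE),
      rf  = matrix(c(50, 23, 20, 119), 2, byrow = TRUE),
      svm = matrix(c(69, 4, 8, 131), 2, byrow = TRUE),
      cnn = matrix(c(71, 2, 2, 137), 2, byrow = TRUE)),
    HC_DCIS = list(
      knn = matrix(c(69, 4, 6, 24), 2, byrow = TRUE),
      rf  = matrix(c(72, 1, 5, 25), 2, byrow = TRUE),
      svm = matrix(c(73, 0, 0, 30), 2, byrow = TRUE),
      cnn = matrix(c(73, 0, 0, 30), 2, byrow = TRUE)),
    BC_DCIS = list(
      knn = matrix(c(133, 6, 8, 22), 2, byrow = TRUE),
      rf  = matrix(c(139, 0, 12, 18), 2, byrow = TRUE),
      svm = matrix(c(139, 0, 0, 30), 2, byrow = TRUE),
      cnn = matrix(c(139, 0, 0, 30), 2, byrow = TRUE)))
}

as_confusion <- function(m, classes) {
  dimnames(m) <- list(true = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

# Mann-Whitney AUC oracle: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
auc_pair_oracle <- function(score, is_pos) {
  sp <- score[is_pos]; sn <- score[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
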