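#' Architecture and training hyperparameters of the 1D CNN
#'
#' Describes the spectral classification network: two unpadded ("valid")
#' kernel-3 convolutions with 8 then 16 channels, one batch-normalization
#' layer between them, tanh activations, a width-3 stride-3 max-pool, then
#' a flatten feeding a dense softmax output. On a length-1698 spectrum the
#' flatten produces 9024 features. Trained with Adam on categorical
#' cross-entropy.
#'
#' @param input_len Spectrum length (default 1698).
#' @param conv_channels Output channels of the two convolutions.
#' @param kernel_len Convolution kernel length.
#' @param pool_len Max-pool width (stride equals width).
#' @param hidden_activation Activation for both convolution outputs
#'   (\code{"tanh"}).
#' @param n_classes Number of output classes.
#' @param batch_size,epochs,learning_rate Training hyperparameters.
#' @param optimizer Only \code{"Adam"} is implemented.
#' @param loss Only \code{"categorical_crossentropy"} is implemented.
#' @return An object of class \code{cnn_spec}.
#' @export
cnn_spec <- function(input_len = 1698, conv_channels = c(8, 16),
                     kernel_len = 3, pool_len = 3,
                     hidden_activation = "tanh", n_classes = 3,
                     batch_size = 16, epochs = 100, learning_rate = 0.001,
                     optimizer = "Adam", loss = "categorical_crossentropy") {
  if (length(conv_channels) != 2 || any(conv_channels < 1))
    stop("'conv_channels' must be two positive counts")
  if (kernel_len < 1 || pool_len < 1) stop("kernel and pool lengths must be >= 1")
  if (n_classes < 2) stop("'n_classes' must be >= 2")
  if (!identical(hidden_activation, "tanh"))
    stop("only the 'tanh' hidden activation is implemented")
  if (!identical(optimizer, "Adam")) stop("only the Adam optimizer is implemented")
  if (!identical(loss, "categorical_crossentropy"))
    stop("only categorical cross-entropy loss is implemented")
  if (batch_size < 1 || epochs < 0 || learning_rate <= 0)
    stop("invalid training hyperparameters")
  spec <- structure(list(input_len = as.integer(input_len),
                         conv_channels = as.integer(conv_channels),
                         kernel_len = as.integer(kernel_len),
                         pool_len = as.integer(pool_len),
                         hidden_activation = hidden_activation,
                         n_classes = as.integer(n_classes),
                         batch_size = as.integer(batch_size),
                         epochs = as.integer(epochs),
                         learning_rate = learning_rate,
                         optimizer = optimizer, loss = loss),
                    class = "cnn_spec")
  flattened_size(spec)  # validates that all intermediate lengths are positive
  spec
}

#' Flattened feature count of the CNN
#'
#' Number of features entering the dense output layer: each valid
#' convolution shortens the signal by \code{kernel_len - 1}, the stride-pool
#' divides by \code{pool_len} with floor, and the result is multiplied by
#' the final channel count. For the default spec on a length-1698 input this
#' is \code{floor(1694 / 3) * 16 = 9024}.
#'
#' @param spec A \code{\link{cnn_spec}}.
#' @return Integer feature count.
#' @examples
#' flattened_size(cnn_spec())  # 9024
#' @export
flattened_size <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  l1 <- spec$input_len - (spec$kernel_len - 1L)
  l2 <- l1 - (spec$kernel_len - 1L)
  p <- l2 %/% spec$pool_len
  if (l1 < 1 || l2 < 1 || p < 1)
    stop("non-positive intermediate length: input too short for this spec")
  as.integer(p * spec$conv_channels[2])
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained CNN
#'
#' Allocates and initializes all weights (Glorot-uniform) and the batch-norm
#' state from the given seed. The flatten size implied by the architecture
#' is checked against the dense layer fan-in.
#'
#' @param spec A \code{\link{cnn_spec}}.
#' @param seed RNG seed for weight initialization.
#' @return An object of class \code{c("raman_cnn", "raman_model")} with
#'   untrained parameters and an empty training history.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1) {
  k <- spec$kernel_len
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  fl <- flattened_size(spec)
  set.seed(seed)
  params <- list(
    W1 = glorot(k, c1, fan_in = k, fan_out = k * c1),
    b1 = numeric(c1),
    gamma = rep(1, c1), beta = numeric(c1),
    W2 = glorot(k * c1, c2, fan_in = k * c1, fan_out = k * c2),
    b2 = numeric(c2),
    W3 = glorot(fl, spec$n_classes, fan_in = fl, fan_out = spec$n_classes),
    b3 = numeric(spec$n_classes))
  stopifnot(nrow(params$W3) == fl)
  structure(list(family = "CNN", spec = spec, params = params,
                 bn = list(mean = numeric(c1), var = rep(1, c1),
                           momentum = 0.9, eps = 1e-5, initialized = FALSE),
                 classes = NULL, seed = seed,
                 history = empty_history()),
            class = c("raman_cnn", "raman_model"))
}

empty_history <- function() {
  data.frame(epoch = integer(0), train_loss = numeric(0),
             train_acc = numeric(0), val_loss = numeric(0),
             val_acc = numeric(0))
}

# im2col for a single-channel batch: X is B x L, result (B*Lout) x k with
# row index r = (p-1)*B + b.
im2col1 <- function(X, k, lout) {
  out <- matrix(0, nrow(X) * lout, k)
  for (t in seq_len(k)) out[, t] <- X[, t:(t + lout - 1)]
  out
}

# im2col for a multi-channel batch held as array (B, L, C); column
# j = (c-1)*k + t.
im2col_mc <- function(A, k, lout) {
  B <- dim(A)[1]; C <- dim(A)[3]
  out <- matrix(0, B * lout, k * C)
  for (cc in seq_len(C))
    for (t in seq_len(k))
      out[, (cc - 1) * k + t] <- A[, t:(t + lout - 1), cc]
  out
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

cnn_dims <- function(spec) {
  l1 <- spec$input_len - (spec$kernel_len - 1L)
  l2 <- l1 - (spec$kernel_len - 1L)
  list(l1 = l1, l2 = l2, p = l2 %/% spec$pool_len)
}

cnn_forward <- function(model, X, train = FALSE) {
  spec <- model$spec; pm <- model$params; bn <- model$bn
  k <- spec$kernel_len; c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  d <- cnn_dims(spec)
  B <- nrow(X)
  Xc1 <- im2col1(X, k, d$l1)
  Z1 <- add_bias(Xc1 %*% pm$W1, pm$b1)              # (B*l1) x c1
  if (train) {
    mu <- colMeans(Z1)
    va <- colMeans(Z1^2) - mu^2
  } else {
    mu <- bn$mean; va <- bn$var
  }
  inv_sd <- 1 / sqrt(va + bn$eps)
  Xhat <- (Z1 - rep(mu, each = nrow(Z1))) * rep(inv_sd, each = nrow(Z1))
  A1 <- tanh(add_bias(Xhat * rep(pm$gamma, each = nrow(Z1)), pm$beta))
  A1arr <- array(A1, c(B, d$l1, c1))
  Xc2 <- im2col_mc(A1arr, k, d$l2)
  A2 <- tanh(add_bias(Xc2 %*% pm$W2, pm$b2))        # (B*l2) x c2
  A2arr <- array(A2, c(B, d$l2, c2))
  pool <- spec$pool_len
  slices <- lapply(seq_len(pool), function(t)
    A2arr[, seq(t, by = pool, length.out = d$p), , drop = FALSE])
  M <- slices[[1]]
  if (pool > 1) for (t in 2:pool) M <- pmax(M, slices[[t]])
  Fl <- matrix(M, B, d$p * c2)
  logits <- add_bias(Fl %*% pm$W3, pm$b3)
  probs <- softmax_rows(logits)
  out <- list(probs = probs)
  if (train)
    out <- c(out, list(Xc1 = Xc1, Xhat = Xhat, inv_sd = inv_sd, A1 = A1,
                       Xc2 = Xc2, A2 = A2, slices = slices, M = M, Fl = Fl,
                       batch_mu = mu, batch_var = va, B = B, dims = d))
  out
}

cnn_backward <- function(model, fw, Y) {
  spec <- model$spec; pm <- model$params
  k <- spec$kernel_len; c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  d <- fw$dims; B <- fw$B; pool <- spec$pool_len
  dlogits <- (fw$probs - Y) / B
  gW3 <- crossprod(fw$Fl, dlogits)
  gb3 <- colSums(dlogits)
  dFl <- dlogits %*% t(pm$W3)
  dM <- array(dFl, c(B, d$p, c2))
  # route pooled gradient to the (first) argmax within each pool window
  dA2arr <- array(0, c(B, d$l2, c2))
  claimed <- array(FALSE, dim(dM))
  for (t in seq_len(pool)) {
    mt <- (fw$slices[[t]] == fw$M) & !claimed
    claimed <- claimed | mt
    idx <- seq(t, by = pool, length.out = d$p)
    dA2arr[, idx, ] <- dA2arr[, idx, ] + dM * mt
  }
  dZ2 <- matrix(dA2arr, B * d$l2, c2) * (1 - fw$A2^2)
  gW2 <- crossprod(fw$Xc2, dZ2)
  gb2 <- colSums(dZ2)
  dXc2 <- dZ2 %*% t(pm$W2)
  dA1arr <- array(0, c(B, d$l1, c1))
  for (cc in seq_len(c1))
    for (t in seq_len(k))
      dA1arr[, t:(t + d$l2 - 1), cc] <- dA1arr[, t:(t + d$l2 - 1), cc] +
        matrix(dXc2[, (cc - 1) * k + t], B, d$l2)
  dA1 <- matrix(dA1arr, B * d$l1, c1) * (1 - fw$A1^2)
  ggamma <- colSums(dA1 * fw$Xhat)
  gbeta <- colSums(dA1)
  n <- nrow(dA1)
  coef <- rep(pm$gamma * fw$inv_sd, each = n)
  dZ1 <- coef * (dA1 - rep(colMeans(dA1), each = n) -
                   fw$Xhat * rep(colMeans(dA1 * fw$Xhat), each = n))
  gW1 <- crossprod(fw$Xc1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
       W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

ce_loss <- function(probs, Y) {
  -mean(rowSums(Y * log(pmax(probs, 1e-12))))
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

cnn_predict_proba <- function(model, X, chunk = 256L) {
  n <- nrow(X)
  out <- matrix(0, n, model$spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- cnn_forward(model, X[i:j, , drop = FALSE])$probs
    i <- j + 1L
  }
  out
}

#' Train the CNN
#'
#' Minimizes categorical cross-entropy with Adam over shuffled mini-batches.
#' A stratified fraction of the training set is held out as a validation set
#' and per-epoch train/validation accuracy and loss are recorded (the train
#' metrics are batch averages over the epoch, the validation metrics are
#' computed in inference mode at each epoch end).
#'
#' @param model An untrained model from \code{\link{build_cnn}}.
#' @param train_set A preprocessed, labelled \code{\link{spectrum_set}} with
#'   at least two classes present.
#' @param val_fraction Stratified fraction held out for the validation
#'   curves (0 disables validation).
#' @param seed Seed governing the validation split and batch shuffling.
#' @param restore_best Keep the weights of the epoch with the highest
#'   validation accuracy (ties broken by lower validation loss) instead of
#'   the last epoch's. A standard guard against late-training oscillation;
#'   selection uses only the validation holdout. Requires
#'   \code{val_fraction > 0}.
#' @return The trained \code{raman_cnn} model with \code{$history} filled
#'   (one row per epoch).
#' @export
train_cnn <- function(model, train_set, val_fraction = 0.2, seed = 1,
                      restore_best = FALSE) {
  stopifnot(inherits(model, "raman_cnn"), inherits(train_set, "spectrum_set"))
  if (is.null(train_set$labels)) stop("training set must be labelled")
  classes <- levels(droplevels(train_set$labels))
  if (length(classes) < 2) stop("training set contains a single class")
  if (length(classes) != model$spec$n_classes)
    stop(sprintf("spec expects %d classes but the data has %d",
                 model$spec$n_classes, length(classes)))
  if (ncol(train_set$intensities) != model$spec$input_len)
    stop("spectrum length does not match spec input_len")
  model$classes <- classes
  X <- train_set$intensities
  y <- droplevels(train_set$labels)
  set.seed(seed)
  n <- nrow(X)
  if (val_fraction > 0) {
    val_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      idx[sample.int(length(idx), max(1L, floor(val_fraction * length(idx))))]
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- one_hot(y[tr_idx], classes)
  Xva <- X[val_idx, , drop = FALSE]; Yva <- one_hot(y[val_idx], classes)
  yva <- y[val_idx]
  if (restore_best && !length(val_idx))
    stop("'restore_best' needs a validation holdout (val_fraction > 0)")
  bsz <- model$spec$batch_size
  state <- adam_init(model$params)
  hist <- vector("list", model$spec$epochs)
  best <- list(va = -Inf, vl = Inf, params = NULL, bn = NULL)
  for (ep in seq_len(model$spec$epochs)) {
    perm <- sample(nrow(Xtr))
    batches <- split(perm, ceiling(seq_along(perm) / bsz))
    bl <- ba <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      ix <- batches[[bi]]
      fw <- cnn_forward(model, Xtr[ix, , drop = FALSE], train = TRUE)
      loss <- ce_loss(fw$probs, Ytr[ix, , drop = FALSE])
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d; try a lower learning rate",
                     ep, bi))
      # exponential running statistics for inference-time batch norm;
      # seeded from the first batch so short trainings are usable
      if (!model$bn$initialized) {
        model$bn$mean <- fw$batch_mu
        model$bn$var <- fw$batch_var
        model$bn$initialized <- TRUE
      } else {
        mom <- model$bn$momentum
        model$bn$mean <- mom * model$bn$mean + (1 - mom) * fw$batch_mu
        model$bn$var <- mom * model$bn$var + (1 - mom) * fw$batch_var
      }
      grads <- cnn_backward(model, fw, Ytr[ix, , drop = FALSE])
      upd <- adam_step(model$params, grads, state, model$spec$learning_rate)
      model$params <- upd$params
      state <- upd$state
      bl[bi] <- loss
      ba[bi] <- mean(max.col(fw$probs, ties.method = "first") ==
                       max.col(Ytr[ix, , drop = FALSE], ties.method = "first"))
    }
    if (length(val_idx)) {
      pv <- cnn_predict_proba(model, Xva)
      vl <- ce_loss(pv, Yva)
      va <- mean(classes[max.col(pv, ties.method = "first")] ==
                   as.character(yva))
    } else {
      vl <- NA_real_; va <- NA_real_
    }
    if (restore_best && (va > best$va || (va == best$va && vl < best$vl))) {
      best <- list(va = va, vl = vl, params = model$params, bn = model$bn)
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(bl),
                             train_acc = mean(ba), val_loss = vl,
                             val_acc = va)
  }
  model$history <- if (model$spec$epochs > 0) do.call(rbind, hist) else
    empty_history()
  if (restore_best && !is.null(best$params)) {
    model$params <- best$params
    model$bn <- best$bn
  }
  if (model$spec$epochs > 0)
    model <- bn_population_stats(model, Xtr)
  model
}

# Inference-time batch-norm statistics: the population mean/variance of the
# pre-normalization activations over the whole training set under the final
# weights (the exponential running average kept during training is only a
# rough tracker; minority-class samples near a decision boundary are
# sensitive to the difference).
bn_population_stats <- function(model, X, chunk = 256L) {
  k <- model$spec$kernel_len
  l1 <- model$spec$input_len - (k - 1L)
  n <- 0; s1 <- 0; s2 <- 0
  i <- 1L
  while (i <= nrow(X)) {
    j <- min(i + chunk - 1L, nrow(X))
    Xc1 <- im2col1(X[i:j, , drop = FALSE], k, l1)
    Z1 <- add_bias(Xc1 %*% model$params$W1, model$params$b1)
    n <- n + nrow(Z1)
    s1 <- s1 + colSums(Z1)
    s2 <- s2 + colSums(Z1^2)
    i <- j + 1L
  }
  model$bn$mean <- s1 / n
  model$bn$var <- pmax(s2 / n - (s1 / n)^2, 0)
  model$bn$initialized <- TRUE
  model
}
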