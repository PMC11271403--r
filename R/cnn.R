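#' Architecture of the self-supervised 1D convolutional network
#'
#' Three one-dimensional convolutional layers (default 8, 20 and 32 filters,
#' kernel size 21 minutes) with max pooling of size and stride 2 after the
#' first layer only, global average pooling down to a vector whose length
#' equals the final filter count (the embedding), dropout on that vector
#' during training, and a single sigmoid output unit. All hidden activations
#' are rectified linear. Training minimizes binary cross-entropy with Adam
#' (learning rate 3e-4) and L2 regularization (weight 1e-8) on every
#' non-bias parameter.
#'
#' @param conv_filters Integer vector of length 3: filters per conv layer.
#' @param kernel_size Kernel length in minutes (all conv layers).
#' @param dropout_p Dropout probability on the pooled embedding.
#' @param learning_rate Adam learning rate.
#' @param l2_weight L2 penalty weight on non-bias parameters.
#' @param batch_size Minibatch size for training.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(conv_filters = c(8L, 20L, 32L), kernel_size = 21L,
                     dropout_p = 0.5, learning_rate = 3e-4,
                     l2_weight = 1e-8, batch_size = 64L) {
  stopifnot(length(conv_filters) == 3, all(conv_filters >= 1),
            kernel_size >= 1, dropout_p >= 0, dropout_p < 1,
            learning_rate > 0, l2_weight >= 0)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = 2L, pool_stride = 2L,
                 dropout_p = dropout_p, learning_rate = learning_rate,
                 l2_weight = l2_weight, batch_size = as.integer(batch_size)),
            class = "cnn_spec")
}

cnn_min_input_len <- function(spec) {
  # final conv needs >= kernel_size inputs; walk the length arithmetic back
  k <- spec$kernel_size
  l3_in <- k                      # conv3 output length >= 1
  l2_in <- l3_in + k - 1L         # conv2
  l1_out <- (l2_in - 1L) * spec$pool_stride + spec$pool_size # pool
  l1_out + k - 1L                 # conv1
}

cnn_layer_lengths <- function(spec, input_len) {
  k <- spec$kernel_size
  l1 <- input_len - k + 1L
  lp <- (l1 - spec$pool_size) %/% spec$pool_stride + 1L
  l2 <- lp - k + 1L
  l3 <- l2 - k + 1L
  list(conv1 = l1, pool = lp, conv2 = l2, conv3 = l3)
}

#' Build the convolutional discriminator network
#'
#' Instantiates the network of [cnn_spec()] for inputs of `input_len`
#' minutes by `n_channels` channels (heart rate, steps, missingness mask),
#' with He-normal weight initialization. The post-global-average-pooling
#' representation -- the patient embedding -- has length
#' `conv_filters[3]`.
#'
#' @param spec A [cnn_spec()].
#' @param input_len Window length in minutes (default 240).
#' @param n_channels Number of input channels (default 3).
#' @param seed Integer seed for weight initialization.
#' @return An `afw_cnn` model object.
#' @examples
#' m <- build_cnn(cnn_spec(), seed = 1)
#' m$embedding_dim
#' @export
build_cnn <- function(spec = cnn_spec(), input_len = 240L, n_channels = 3L,
                      seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  min_len <- cnn_min_input_len(spec)
  if (input_len < min_len) {
    stop(sprintf("input_len %d is shorter than the kernel chain; minimum is %d",
                 input_len, min_len), call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- spec$kernel_size
  f <- spec$conv_filters
  he <- function(fan_in, n_out) {
    matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
  }
  params <- list(
    W1 = he(k * n_channels, f[1]), b1 = numeric(f[1]),
    W2 = he(k * f[1], f[2]),       b2 = numeric(f[2]),
    W3 = he(k * f[2], f[3]),       b3 = numeric(f[3]),
    Wd = he(f[3], 1L),             bd = 0
  )
  structure(list(spec = spec, input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels), params = params,
                 embedding_dim = f[3],
                 lengths = cnn_layer_lengths(spec, as.integer(input_len))),
            class = "afw_cnn")
}

#' @export
print.afw_cnn <- function(x, ...) {
  cat(sprintf("<afw_cnn> %d x %d input -> conv(%s, k=%d) -> embedding %d -> sigmoid (%d parameters)\n",
              x$input_len, x$n_channels,
              paste(x$spec$conv_filters, collapse = "/"),
              x$spec$kernel_size, x$embedding_dim, cnn_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a CNN model
#' @param model An `afw_cnn`.
#' @return Integer parameter count (weights + biases).
#' @export
cnn_n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# (B, L, C) array -> (B * Lout, K * C) patch matrix; column (k-1)*C + c is
# channel c at kernel offset k.
im2col <- function(A, K) {
  d <- dim(A)
  B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - K + 1L
  Xc <- array(0, c(B, Lout, K * C))
  for (k in seq_len(K)) {
    Xc[, , ((k - 1L) * C + 1L):(k * C)] <- A[, k:(k + Lout - 1L), , drop = FALSE]
  }
  dim(Xc) <- c(B * Lout, K * C)
  Xc
}

col2im <- function(dXc, B, L, C, K) {
  Lout <- L - K + 1L
  dim(dXc) <- c(B, Lout, K * C)
  dA <- array(0, c(B, L, C))
  for (k in seq_len(K)) {
    dA[, k:(k + Lout - 1L), ] <- dA[, k:(k + Lout - 1L), , drop = FALSE] +
      dXc[, , ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  dA
}

conv_forward <- function(A, W, b, K) {
  d <- dim(A)
  Xc <- im2col(A, K)
  Z <- sweep(Xc %*% W, 2, b, "+")
  list(Z = array(Z, c(d[1], d[2] - K + 1L, ncol(W))), Xc = Xc)
}

# Forward pass. With training = TRUE a dropout mask is sampled (from the
# current RNG state) and a full cache for backprop is returned.
cnn_forward <- function(model, X, training = FALSE) {
  p <- model$params
  sp <- model$spec
  K <- sp$kernel_size
  B <- dim(X)[1]

  c1 <- conv_forward(X, p$W1, p$b1, K)
  A1 <- pmax(c1$Z, 0)
  L1 <- dim(A1)[2]
  Lp <- model$lengths$pool
  a <- A1[, seq(1L, by = 2L, length.out = Lp), , drop = FALSE]
  b2_ <- A1[, seq(2L, by = 2L, length.out = Lp), , drop = FALSE]
  P <- pmax(a, b2_)
  take_first <- a >= b2_

  c2 <- conv_forward(P, p$W2, p$b2, K)
  A2 <- pmax(c2$Z, 0)
  c3 <- conv_forward(A2, p$W3, p$b3, K)
  A3 <- pmax(c3$Z, 0)

  L3 <- dim(A3)[2]
  G <- colMeans(aperm(A3, c(2, 1, 3)))          # (B, F3)
  if (B == 1) G <- matrix(G, nrow = 1)

  if (training && sp$dropout_p > 0) {
    mask <- matrix(stats::rbinom(length(G), 1, 1 - sp$dropout_p) /
                     (1 - sp$dropout_p), nrow(G), ncol(G))
  } else {
    mask <- NULL
  }
  Gd <- if (is.null(mask)) G else G * mask
  logits <- as.numeric(Gd %*% p$Wd + p$bd)
  probs <- 1 / (1 + exp(-logits))
  out <- list(probs = probs, embedding = G)
  if (training) {
    out$cache <- list(X = X, Xc1 = c1$Xc, Z1 = c1$Z, take_first = take_first,
                      P = P, Xc2 = c2$Xc, Z2 = c2$Z, Xc3 = c3$Xc, Z3 = c3$Z,
                      G = G, mask = mask, Gd = Gd, L1 = L1, Lp = Lp, L3 = L3)
  }
  out
}

cnn_loss <- function(probs, y) {
  eps <- 1e-12
  -mean(y * log(probs + eps) + (1 - y) * log(1 - probs + eps))
}

cnn_backward <- function(model, fw, y) {
  p <- model$params
  sp <- model$spec
  K <- sp$kernel_size
  cache <- fw$cache
  B <- length(y)
  l2 <- sp$l2_weight

  dlogit <- (fw$probs - y) / B                       # (B)
  dWd <- crossprod(cache$Gd, dlogit) + 2 * l2 * p$Wd
  dbd <- sum(dlogit)
  dGd <- dlogit %*% t(p$Wd)                          # (B, F3)
  dG <- if (is.null(cache$mask)) dGd else dGd * cache$mask

  L3 <- cache$L3
  F3 <- ncol(dG)
  dA3 <- aperm(array(dG / L3, c(B, F3, L3)), c(1, 3, 2))
  dZ3 <- dA3 * (cache$Z3 > 0)
  dZ3m <- dZ3; dim(dZ3m) <- c(B * L3, F3)
  dW3 <- crossprod(cache$Xc3, dZ3m) + 2 * l2 * p$W3
  db3 <- colSums(dZ3m)

  L2l <- dim(cache$Z2)[2]
  dA2 <- col2im(dZ3m %*% t(p$W3), B, L2l, ncol(p$W2), K)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dZ2m <- dZ2; dim(dZ2m) <- c(B * L2l, ncol(p$W2))
  dW2 <- crossprod(cache$Xc2, dZ2m) + 2 * l2 * p$W2
  db2 <- colSums(dZ2m)

  Lp <- cache$Lp
  dP <- col2im(dZ2m %*% t(p$W2), B, Lp, ncol(p$W1), K)
  L1 <- cache$L1
  F1 <- ncol(p$W1)
  dA1 <- array(0, c(B, L1, F1))
  dA1[, seq(1L, by = 2L, length.out = Lp), ] <- dP * cache$take_first
  dA1[, seq(2L, by = 2L, length.out = Lp), ] <-
    dA1[, seq(2L, by = 2L, length.out = Lp), , drop = FALSE] +
    dP * !cache$take_first
  dZ1 <- dA1 * (cache$Z1 > 0)
  dZ1m <- dZ1; dim(dZ1m) <- c(B * L1, F1)
  dW1 <- crossprod(cache$Xc1, dZ1m) + 2 * l2 * p$W1
  db1 <- colSums(dZ1m)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       Wd = dWd, bd = dbd)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the CNN discriminator on labelled windows
#'
#' Minibatch Adam training with binary cross-entropy, epoch-level
#' reshuffling, and optional early stopping on a validation set: training
#' halts when the validation loss has not improved for `patience` epochs and
#' the best-validation-loss parameters are restored.
#'
#' @param model An `afw_cnn` from [build_cnn()].
#' @param X Array `n x input_len x n_channels` of training windows.
#' @param y 0/1 labels (1 = original sample, 0 = scrambled).
#' @param X_val,y_val Optional validation windows and labels.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); ignored without a validation set.
#' @param seed Integer seed (shuffling and dropout).
#' @return The trained model, with a `history` data frame (`epoch`,
#'   `train_loss`, `val_loss`, `val_accuracy`) attached.
#' @export
cnn_train <- function(model, X, y, X_val = NULL, y_val = NULL,
                      epochs = 200L, patience = 10L, seed = 1L) {
  stopifnot(inherits(model, "afw_cnn"), dim(X)[1] == length(y))
  set.seed(as.integer(seed))
  sp <- model$spec
  n <- length(y)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- vector("list", epochs)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = sp$batch_size)) {
      idx <- ord[start:min(start + sp$batch_size - 1L, n)]
      fw <- cnn_forward(model, X[idx, , , drop = FALSE], training = TRUE)
      losses <- c(losses, cnn_loss(fw$probs, y[idx]))
      gr <- cnn_backward(model, fw, y[idx])
      upd <- adam_step(model$params, gr, state, sp$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(X_val)) {
      pv <- cnn_forward(model, X_val)$probs
      val_loss <- cnn_loss(pv, y_val)
      val_acc <- mean((pv > 0.5) == (y_val == 1))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = model$params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_loss = val_loss, val_accuracy = val_acc)
    if (!is.null(X_val) && stale >= patience) break
  }
  if (!is.null(X_val)) model$params <- best$params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$epochs_run <- nrow(model$history)
  model
}

#' Predicted probability that windows are original (not scrambled)
#' @param model A trained `afw_cnn`.
#' @param X Array `n x input_len x n_channels`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
cnn_predict <- function(model, X) {
  cnn_forward(model, X)$probs
}

#' Post-pooling embeddings of windows
#'
#' Runs the network with dropout and the classification head removed and
#' returns the global-average-pooled representation of the final
#' convolutional layer for each window.
#'
#' @param model A trained `afw_cnn`.
#' @param X Array `n x input_len x n_channels`.
#' @return Matrix `n x embedding_dim`.
#' @export
cnn_embed <- function(model, X) {
  cnn_forward(model, X)$embedding
}
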