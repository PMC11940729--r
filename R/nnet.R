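# One-dimensional CNN on the 39-feature vector, implemented directly with
# matrix operations: conv(1->16, k=2, stride 1, same-length) -> ReLU ->
# maxpool(2) -> conv(16->32, k=2, same) -> ReLU -> maxpool(2) -> flatten ->
# FC(4096) -> ReLU -> dropout -> FC(256) -> ReLU -> dropout -> FC(n_classes),
# trained with softmax cross-entropy and Adam with a step decay schedule.
# Same-length padding with kernel 2 pads one position at the sequence end.

#' Model training configuration
#'
#' Architecture and optimizer constants default to the canonical values:
#' conv channels (16, 32), kernel 2, stride 1, same-length padding, max
#' pooling of size/stride 2, fully connected widths (4096, 256), ReLU
#' activations, softmax cross-entropy loss, Adam with learning rate 0.001
#' and beta1 = 0.9, beta2 = 0.999, and a scheduler multiplying the learning
#' rate by 0.9 every 10 epochs. Dropout probability, epoch count and batch
#' size are tunable.
#'
#' @param n_classes Number of classes (2 or 3).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam momentum parameters.
#' @param step_size,gamma Learning-rate schedule: multiply by `gamma` every
#'   `step_size` epochs.
#' @param dropout Dropout probability after FC1 and FC2.
#' @param fc_dims Widths of the two hidden fully connected layers.
#' @param conv_channels Output channels of the two convolutional layers.
#' @param kernel_size Convolution kernel width.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return A list of class `"oc_model_config"`.
#' @export
model_config <- function(n_classes = 3, epochs = 100, batch_size = 16,
                         lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         step_size = 10, gamma = 0.9, dropout = 0.5,
                         fc_dims = c(4096, 256), conv_channels = c(16, 32),
                         kernel_size = 2, seed = 1) {
  structure(as.list(environment()), class = "oc_model_config")
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build the 1D convolutional network
#'
#' For 39 input features the sequence lengths are 39 -> 19 -> 9 under
#' same-length convolution and floor pooling, giving a flattened width of
#' 32 x 9 = 288.
#'
#' @param config An `oc_model_config`.
#' @param n_features Input feature count (>= 4 so that two poolings leave a
#'   non-empty map).
#' @return An untrained model of class `"oc_model"`, arch `"cnn"`.
#' @export
build_cnn <- function(config, n_features) {
  if (n_features < 4) stop("need at least 4 features for two pooling stages")
  K <- config$kernel_size
  ch <- config$conv_channels
  L <- n_features
  L1 <- L %/% 2L
  L2 <- L1 %/% 2L
  if (L2 < 1) stop("input too short for two pooling stages")
  flat <- ch[2] * L2
  withr_seed(config$seed, {
    params <- list(
      W1 = array(stats::rnorm(1 * ch[1] * K, 0, sqrt(2 / (1 * K))),
                 c(1, ch[1], K)),
      b1 = numeric(ch[1]),
      W2 = array(stats::rnorm(ch[1] * ch[2] * K, 0, sqrt(2 / (ch[1] * K))),
                 c(ch[1], ch[2], K)),
      b2 = numeric(ch[2]),
      Wf1 = he_init(flat, config$fc_dims[1], flat),
      bf1 = numeric(config$fc_dims[1]),
      Wf2 = he_init(config$fc_dims[1], config$fc_dims[2], config$fc_dims[1]),
      bf2 = numeric(config$fc_dims[2]),
      Wf3 = he_init(config$fc_dims[2], config$n_classes, config$fc_dims[2]),
      bf3 = numeric(config$n_classes))
    structure(list(arch = "cnn", config = config, params = params,
                   n_features = n_features, n_classes = config$n_classes,
                   dims = list(L = L, L1 = L1, L2 = L2, flat = flat)),
              class = "oc_model")
  })
}

#' Build the fully connected ablation network
#'
#' Identical fully connected stack (n_features -> 4096 -> 256 -> n_classes)
#' with ReLU and dropout but no convolution/pooling; same loss, optimizer
#' and scheduler.
#'
#' @inheritParams build_cnn
#' @return An untrained model of class `"oc_model"`, arch `"fcnn"`.
#' @export
build_fcnn <- function(config, n_features) {
  withr_seed(config$seed, {
    params <- list(
      Wf1 = he_init(n_features, config$fc_dims[1], n_features),
      bf1 = numeric(config$fc_dims[1]),
      Wf2 = he_init(config$fc_dims[1], config$fc_dims[2], config$fc_dims[1]),
      bf2 = numeric(config$fc_dims[2]),
      Wf3 = he_init(config$fc_dims[2], config$n_classes, config$fc_dims[2]),
      bf3 = numeric(config$n_classes))
    structure(list(arch = "fcnn", config = config, params = params,
                   n_features = n_features, n_classes = config$n_classes),
              class = "oc_model")
  })
}

#' Total trainable parameter count
#' @param model An `oc_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- conv / pool primitives (batch-major arrays: B x C x L) ---------------

# kernel-offset slice of a (Cin, Cout, K) weight array as a Cin x Cout
# matrix (plain indexing would drop a unit Cin dimension)
wslice <- function(W, k) matrix(W[, , k], dim(W)[1], dim(W)[2])

conv1d_forward <- function(A, W, b) {
  d <- dim(A)
  B <- d[1]; Cin <- d[2]; L <- d[3]
  Apad <- array(0, c(B, Cin, L + 1L))
  Apad[, , 1:L] <- A
  X0 <- matrix(aperm(Apad[, , 1:L, drop = FALSE], c(1, 3, 2)), ncol = Cin)
  X1 <- matrix(aperm(Apad[, , 2:(L + 1L), drop = FALSE], c(1, 3, 2)),
               ncol = Cin)
  Y <- X0 %*% wslice(W, 1) + X1 %*% wslice(W, 2)
  Y <- sweep(Y, 2, b, "+")
  Cout <- dim(W)[2]
  out <- aperm(array(Y, c(B, L, Cout)), c(1, 3, 2))
  list(out = out, X0 = X0, X1 = X1)
}

conv1d_backward <- function(dOut, cache, W, dims) {
  B <- dims[1]; Cin <- dims[2]; L <- dims[3]
  Cout <- dim(W)[2]
  dY <- matrix(aperm(dOut, c(1, 3, 2)), ncol = Cout)
  dW <- array(0, dim(W))
  dW[, , 1] <- crossprod(cache$X0, dY)
  dW[, , 2] <- crossprod(cache$X1, dY)
  db <- colSums(dY)
  dX0 <- tcrossprod(dY, wslice(W, 1))
  dX1 <- tcrossprod(dY, wslice(W, 2))
  dApad <- array(0, c(B, Cin, L + 1L))
  dApad[, , 1:L] <- dApad[, , 1:L, drop = FALSE] +
    aperm(array(dX0, c(B, L, Cin)), c(1, 3, 2))
  dApad[, , 2:(L + 1L)] <- dApad[, , 2:(L + 1L), drop = FALSE] +
    aperm(array(dX1, c(B, L, Cin)), c(1, 3, 2))
  list(dA = dApad[, , 1:L, drop = FALSE], dW = dW, db = db)
}

maxpool2_forward <- function(A) {
  d <- dim(A)
  L2 <- d[3] %/% 2L
  A1 <- A[, , 2 * seq_len(L2) - 1L, drop = FALSE]
  A2 <- A[, , 2 * seq_len(L2), drop = FALSE]
  takefirst <- A1 >= A2
  list(out = ifelse(takefirst, A1, A2), takefirst = takefirst, L2 = L2,
       din = d)
}

maxpool2_backward <- function(dOut, cache) {
  dA <- array(0, cache$din)
  L2 <- cache$L2
  d1 <- dOut * cache$takefirst
  d2 <- dOut * !cache$takefirst
  dA[, , 2 * seq_len(L2) - 1L] <- d1
  dA[, , 2 * seq_len(L2)] <- d2
  dA
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. X: B x n_features matrix. Returns logits and a cache for
# backprop. Dropout masks are drawn from the current RNG when train=TRUE.
nn_forward <- function(model, X, train = FALSE) {
  p <- model$params
  cfg <- model$config
  cache <- list()
  B <- nrow(X)
  if (model$arch == "cnn") {
    A0 <- array(X, c(B, 1L, ncol(X)))
    c1 <- conv1d_forward(A0, p$W1, p$b1)
    r1 <- pmax(c1$out, 0)
    p1 <- maxpool2_forward(r1)
    c2 <- conv1d_forward(p1$out, p$W2, p$b2)
    r2 <- pmax(c2$out, 0)
    p2 <- maxpool2_forward(r2)
    H0 <- matrix(p2$out, nrow = B)
    cache <- list(A0dim = dim(A0), c1 = c1, r1 = r1, p1 = p1,
                  c2 = c2, r2 = r2, p2 = p2, p1dim = dim(p1$out))
  } else {
    H0 <- X
  }
  Z1 <- sweep(H0 %*% p$Wf1, 2, p$bf1, "+")
  A1 <- pmax(Z1, 0)
  M1 <- if (train && cfg$dropout > 0) {
    matrix(stats::rbinom(length(A1), 1, 1 - cfg$dropout), nrow(A1)) /
      (1 - cfg$dropout)
  } else 1
  D1 <- A1 * M1
  Z2 <- sweep(D1 %*% p$Wf2, 2, p$bf2, "+")
  A2 <- pmax(Z2, 0)
  M2 <- if (train && cfg$dropout > 0) {
    matrix(stats::rbinom(length(A2), 1, 1 - cfg$dropout), nrow(A2)) /
      (1 - cfg$dropout)
  } else 1
  D2 <- A2 * M2
  logits <- sweep(D2 %*% p$Wf3, 2, p$bf3, "+")
  c(cache, list(H0 = H0, Z1 = Z1, A1 = A1, M1 = M1, D1 = D1,
                Z2 = Z2, A2 = A2, M2 = M2, D2 = D2, logits = logits))
}

# Softmax cross-entropy loss and parameter gradients for one batch.
# y: integer labels in 1..n_classes.
nn_loss_grads <- function(model, X, y, train = FALSE) {
  p <- model$params
  cache <- nn_forward(model, X, train = train)
  B <- nrow(X)
  P <- softmax(cache$logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), y)] + eps))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  g <- list()
  g$Wf3 <- crossprod(cache$D2, dZ)
  g$bf3 <- colSums(dZ)
  dD2 <- tcrossprod(dZ, p$Wf3)
  dA2 <- dD2 * cache$M2
  dZ2 <- dA2 * (cache$Z2 > 0)
  g$Wf2 <- crossprod(cache$D1, dZ2)
  g$bf2 <- colSums(dZ2)
  dD1 <- tcrossprod(dZ2, p$Wf2)
  dA1 <- dD1 * cache$M1
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$Wf1 <- crossprod(cache$H0, dZ1)
  g$bf1 <- colSums(dZ1)
  dH0 <- tcrossprod(dZ1, p$Wf1)
  if (model$arch == "cnn") {
    dP2 <- array(dH0, dim(cache$p2$out))
    dR2 <- maxpool2_backward(dP2, cache$p2)
    dC2 <- dR2 * (cache$c2$out > 0)
    bw2 <- conv1d_backward(dC2, cache$c2, p$W2, cache$p1dim)
    g$W2 <- bw2$dW
    g$b2 <- bw2$db
    dP1 <- bw2$dA
    dR1 <- maxpool2_backward(dP1, cache$p1)
    dC1 <- dR1 * (cache$c1$out > 0)
    bw1 <- conv1d_backward(dC1, cache$c1, p$W1, cache$A0dim)
    g$W1 <- bw1$dW
    g$b1 <- bw1$db
  }
  list(loss = loss, grads = g[names(p)])
}

#' Train a model
#'
#' Neural models (`cnn`, `fcnn`) are trained by mini-batch gradient descent
#' with Adam under softmax cross-entropy; the learning rate is multiplied by
#' `gamma` (default 0.9) every `step_size` (default 10) epochs. All
#' randomness -- initialization, shuffling, dropout -- derives from the
#' config seed, so identical seeds give identical loss histories. Baseline
#' models (`svm`, `rf`) are fitted by their libraries under the model seed.
#'
#' @param model An `oc_model` from [build_cnn()], [build_fcnn()] or
#'   [build_baseline()].
#' @param X Numeric matrix (rows = participants, columns = normalized
#'   features).
#' @param y Class labels: factor or integer vector.
#' @return The trained model; neural models carry `loss_history` (one mean
#'   loss per epoch) and `lr_history`.
#' @export
train_model <- function(model, X, y) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in X")
  yf <- as.factor(y)
  model$class_levels <- levels(yf)
  yi <- as.integer(yf)
  if (model$arch %in% c("svm", "rf")) return(train_baseline(model, X, yf))
  if (nlevels(yf) != model$n_classes)
    stop("label count does not match model n_classes")
  cfg <- model$config
  p <- lapply(model$params, function(w) w + 0)  # force uniquely owned copies
  m <- lapply(p, function(w) w * 0)
  v <- lapply(p, function(w) w * 0)
  tstep <- 0
  n <- nrow(X)
  loss_hist <- lr_hist <- numeric(cfg$epochs)
  withr_seed(derive_seed(cfg$seed, 17L), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr * cfg$gamma^((epoch - 1) %/% cfg$step_size)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      eloss <- 0
      for (bi in batches) {
        model$params <- p
        lg <- nn_loss_grads(model, X[bi, , drop = FALSE], yi[bi],
                            train = TRUE)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch)
        tstep <- tstep + 1
        for (nm in names(p))
          .adam_step(p[[nm]], m[[nm]], v[[nm]], lg$grads[[nm]],
                     lr, cfg$beta1, cfg$beta2, 1e-8,
                     1 - cfg$beta1^tstep, 1 - cfg$beta2^tstep)
        eloss <- eloss + lg$loss * length(bi)
      }
      loss_hist[epoch] <- eloss / n
      lr_hist[epoch] <- lr
    }
  })
  model$params <- p
  model$loss_history <- loss_hist
  model$lr_history <- lr_hist
  model$trained <- TRUE
  model
}

#' Per-row class probabilities
#'
#' Softmax readout of the final layer for neural models; the library's
#' probability output for baselines. Rows sum to 1; the predicted label is
#' the argmax. Columns are named by class level.
#'
#' @param model A trained `oc_model`.
#' @param X Feature matrix normalized with the training-fold normalizer.
#' @return Matrix of probabilities, one column per class.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (model$arch %in% c("svm", "rf")) return(predict_baseline(model, X))
  if (ncol(X) != model$n_features)
    stop("feature count mismatch: model expects ", model$n_features)
  P <- softmax(nn_forward(model, X, train = FALSE)$logits)
  colnames(P) <- model$class_levels
  P
}

#' Predicted class labels
#' @inheritParams predict_proba
#' @return Character vector of predicted class levels.
#' @export
predict_label <- function(model, X) {
  P <- predict_proba(model, X)
  colnames(P)[max.col(P, ties.method = "first")]
}

#' Build a baseline classifier
#'
#' Standard implementations at library defaults: a radial-kernel support
#' vector machine with probability estimates (e1071) or a random forest
#' (randomForest), both seeded for reproducibility.
#'
#' @param kind `"svm"` or `"rf"`.
#' @param seed Integer seed used when fitting.
#' @return An untrained `oc_model`.
#' @export
build_baseline <- function(kind = c("svm", "rf"), seed = 1) {
  kind <- match.arg(kind)
  structure(list(arch = kind, seed = as.integer(seed)), class = "oc_model")
}

train_baseline <- function(model, X, yf) {
  withr_seed(model$seed, {
    if (model$arch == "svm") {
      model$fit <- e1071::svm(X, yf, probability = TRUE)
    } else {
      model$fit <- randomForest::randomForest(X, yf)
    }
  })
  model$trained <- TRUE
  model
}

predict_baseline <- function(model, X) {
  if (model$arch == "svm") {
    pr <- stats::predict(model$fit, X, probability = TRUE)
    P <- attr(pr, "probabilities")
  } else {
    P <- stats::predict(model$fit, X, type = "prob")
  }
  P[, model$class_levels, drop = FALSE]
}

#' @export
print.oc_model <- function(x, ...) {
  cat(sprintf("<oc_model> arch=%s%s%s\n", x$arch,
              if (!is.null(x$n_features))
                sprintf(" features=%d classes=%d", x$n_features,
                        x$n_classes) else "",
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}
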