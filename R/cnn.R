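#' @title A small 1-D convolutional network for sequence-context classification
#' @description The network that produces the DL score: 1-3 convolutional
#'   layers (ReLU, dropout) sliding along the nucleotide axis of the
#'   channels-first encoded input, followed by 1-3 fully connected layers
#'   and a sigmoid driver-probability head, trained with Adam on binary
#'   cross-entropy. Implemented directly with vectorised matrix algebra
#'   (im2col) so that training is deterministic under a seed.
#' @name cnn
NULL

#' Specify one CNN architecture
#'
#' @param conv_filters integer vector (length 1-3) of filters per
#'   convolutional layer; each value a power of 2 in `[2, 256]`.
#' @param dense_widths integer vector (length 0-3) of hidden fully
#'   connected widths, same value constraint; the sigmoid output head is
#'   always appended and is not listed here.
#' @param kernel convolution kernel length along the sequence axis
#'   (default 3).
#' @param dropout dropout rate applied between layers during training
#'   (default 0.25).
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(conv_filters, dense_widths = integer(0),
                              kernel = 3L, dropout = 0.25) {
  conv_filters <- as.integer(conv_filters)
  dense_widths <- as.integer(dense_widths)
  check_widths <- function(v, what, min_len) {
    if (length(v) < min_len || length(v) > 3L) {
      stop(what, " must list between ", min_len, " and 3 layers")
    }
    bad <- v[v < 2L | v > 256L | bitwAnd(v, v - 1L) != 0L]
    if (length(bad) > 0L) {
      stop(what, " values must be powers of 2 in [2, 256]; got ",
           paste(bad, collapse = ", "))
    }
  }
  check_widths(conv_filters, "conv_filters", 1L)
  if (length(dense_widths) > 0L) check_widths(dense_widths, "dense_widths", 1L)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(
    list(conv_filters = conv_filters, dense_widths = dense_widths,
         kernel = as.integer(kernel), dropout = dropout),
    class = "architecture_spec"
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("CNN architecture: conv(%s) -> dense(%s) -> sigmoid, kernel %d, dropout %.2f\n",
              paste(x$conv_filters, collapse = ","),
              if (length(x$dense_widths)) paste(x$dense_widths, collapse = ",") else "-",
              x$kernel, x$dropout))
  invisible(x)
}

#' Training configuration for the CNN stage
#'
#' @param epochs training epochs (default 100).
#' @param folds cross-validation folds (default 3).
#' @param holdout stratified holdout fraction set aside before CV
#'   (default 0.20).
#' @param batch minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed controlling splits, initialization, shuffling and
#'   dropout.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 100L, folds = 3L, holdout = 0.20,
                            batch = 32L, lr = 1e-3, seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  if (holdout <= 0 || holdout >= 1) stop("holdout fraction must be in (0, 1)")
  structure(
    list(epochs = as.integer(epochs), folds = as.integer(folds),
         holdout = holdout, batch = as.integer(batch), lr = lr,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

## ---- network internals ------------------------------------------------

# im2col for a batch X of dim (n, C, L) and kernel k: returns the
# (n*Lo) x (C*k) matrix whose row (i-1)*Lo + t holds the receptive field
# of output position t for sample i.
im2col <- function(X, k) {
  n <- dim(X)[1]; C <- dim(X)[2]; L <- dim(X)[3]
  Lo <- L - k + 1L
  M <- matrix(0, nrow = n * Lo, ncol = C * k)
  for (c in seq_len(C)) {
    Xc <- X[, c, , drop = TRUE]
    if (n == 1L) Xc <- matrix(Xc, nrow = 1L)
    for (j in seq_len(k)) {
      M[, (c - 1L) * k + j] <- as.vector(t(Xc[, j:(j + Lo - 1L), drop = FALSE]))
    }
  }
  M
}

col2im <- function(dM, n, C, L, k) {
  Lo <- L - k + 1L
  dX <- array(0, dim = c(n, C, L))
  for (c in seq_len(C)) {
    acc <- matrix(0, nrow = n, ncol = L)
    for (j in seq_len(k)) {
      v <- dM[, (c - 1L) * k + j]
      acc[, j:(j + Lo - 1L)] <- acc[, j:(j + Lo - 1L)] + t(matrix(v, nrow = Lo))
    }
    dX[, c, ] <- acc
  }
  dX
}

# He-uniform initialisation
init_mat <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  matrix(stats::runif(nin * nout, -lim, lim), nrow = nin, ncol = nout)
}

cnn_init <- function(arch, C, L) {
  layers <- list()
  for (f in arch$conv_filters) {
    k <- min(arch$kernel, L)
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = k, C_in = C, C_out = f,
      W = init_mat(C * k, f), b = rep(0, f), L_in = L)
    L <- L - k + 1L
    C <- f
  }
  flat <- C * L
  nin <- flat
  for (h in arch$dense_widths) {
    layers[[length(layers) + 1L]] <- list(type = "dense", W = init_mat(nin, h),
                                          b = rep(0, h), act = "relu")
    nin <- h
  }
  layers[[length(layers) + 1L]] <- list(type = "dense", W = init_mat(nin, 1L),
                                        b = 0, act = "sigmoid")
  list(layers = layers, C0 = dim_first <- NULL, flat = flat)
}

#' Number of trainable parameters of an architecture
#' @param arch an `architecture_spec`.
#' @param C,L input channel count and sequence length.
#' @return integer parameter count.
#' @export
n_parameters <- function(arch, C, L) {
  total <- 0L
  for (f in arch$conv_filters) {
    k <- min(arch$kernel, L)
    total <- total + (C * k + 1L) * f
    L <- L - k + 1L; C <- f
  }
  nin <- C * L
  for (h in arch$dense_widths) { total <- total + (nin + 1L) * h; nin <- h }
  total + (nin + 1L) * 1L
}

sigm <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# forward pass; when train = TRUE applies inverted dropout and caches
# intermediates for backprop
cnn_forward <- function(net, X, dropout = 0, train = FALSE) {
  cache <- list()
  A <- X                                   # (n, C, L) until flatten
  n <- dim(X)[1]
  flat_done <- FALSE
  Aflat <- NULL
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      L_in <- dim(A)[3]; C_in <- dim(A)[2]
      M <- im2col(A, ly$k)
      Z <- sweep(M %*% ly$W, 2, ly$b, "+")
      Lo <- L_in - ly$k + 1L
      Arr <- aperm(array(Z, dim = c(Lo, n, ly$C_out)), c(2, 3, 1))
      R <- Arr; R[R < 0] <- 0                    # ReLU
      mask <- NULL
      if (train && dropout > 0) {
        mask <- array(stats::rbinom(length(R), 1, 1 - dropout) / (1 - dropout),
                      dim = dim(R))
        R <- R * mask
      }
      cache[[li]] <- list(M = M, Z = Arr, mask = mask,
                          n = n, C_in = C_in, L_in = L_in)
      A <- R
    } else {
      if (!flat_done) {
        Aflat <- matrix(A, nrow = n)             # flatten (n, C, L) -> n x (C*L)
        flat_done <- TRUE
      }
      Z <- sweep(Aflat %*% ly$W, 2, ly$b, "+")
      if (ly$act == "relu") {
        R <- Z; R[R < 0] <- 0
        mask <- NULL
        if (train && dropout > 0) {
          mask <- matrix(stats::rbinom(length(R), 1, 1 - dropout) / (1 - dropout),
                         nrow = nrow(R))
          R <- R * mask
        }
        cache[[li]] <- list(A_in = Aflat, Z = Z, mask = mask)
        Aflat <- R
      } else {
        cache[[li]] <- list(A_in = Aflat, Z = Z)
        Aflat <- sigm(Z)
      }
    }
  }
  list(prob = as.numeric(Aflat), cache = cache)
}

# backward pass for binary cross-entropy; returns gradients per layer
cnn_backward <- function(net, fwd, y) {
  n <- length(y)
  grads <- vector("list", length(net$layers))
  # d(BCE)/dz for sigmoid output = (p - y)/n
  delta <- matrix((fwd$prob - y) / n, ncol = 1)
  conv_idx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  last_conv <- if (length(conv_idx)) max(conv_idx) else 0L
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    cc <- fwd$cache[[li]]
    if (ly$type == "dense") {
      grads[[li]] <- list(W = crossprod(cc$A_in, delta), b = colSums(delta))
      delta <- delta %*% t(ly$W)
      # through the preceding activation (handled by the producer below)
      if (li - 1L >= 1L && net$layers[[li - 1L]]$type == "dense") {
        pc <- fwd$cache[[li - 1L]]
        relu_g <- (pc$Z > 0) * 1
        if (!is.null(pc$mask)) relu_g <- relu_g * pc$mask
        delta <- delta * relu_g
      } else if (last_conv >= 1L) {
        # delta is w.r.t. flattened conv output: reshape to (n, C, L) and
        # apply the conv layer's ReLU/dropout gradient
        pc <- fwd$cache[[last_conv]]
        Lo <- pc$L_in - net$layers[[last_conv]]$k + 1L
        D <- array(delta, dim = c(nrow(delta), net$layers[[last_conv]]$C_out, Lo))
        relu_g <- (pc$Z > 0) * 1
        if (!is.null(pc$mask)) relu_g <- relu_g * pc$mask
        delta <- D * relu_g
      }
    } else {
      # delta is (n, C_out, Lo) already gated by this layer's activation
      Lo <- cc$L_in - ly$k + 1L
      dZ <- matrix(aperm(delta, c(3, 1, 2)), nrow = cc$n * Lo)
      grads[[li]] <- list(W = crossprod(cc$M, dZ), b = colSums(dZ))
      if (li > 1L) {
        dM <- dZ %*% t(ly$W)
        dX <- col2im(dM, cc$n, cc$C_in, cc$L_in, ly$k)
        pc <- fwd$cache[[li - 1L]]
        relu_g <- (pc$Z > 0) * 1
        if (!is.null(pc$mask)) relu_g <- relu_g * pc$mask
        delta <- dX * relu_g
      }
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]; s <- state[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[li]]$W <- net$layers[[li]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[li]]$b <- net$layers[[li]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[li]] <- s
  }
  list(net = net, state = state)
}

# metrics of probabilistic predictions at the 0.5 threshold
prob_metrics <- function(y, p) {
  pred <- as.integer(p >= 0.5)
  cc <- confusion(y, pred)
  rep <- classification_report(cc)
  auc <- if (length(unique(y)) == 2L) roc_auc(y, p)$auc else NA_real_
  c(accuracy = rep$accuracy, f1 = rep$f1, auc = auc)
}

# train one network on (x, y), tracking per-epoch validation metrics and
# snapshotting the weights of the best-F1 epoch (earliest epoch wins ties)
cnn_fit <- function(x, y, arch, cfg, x_val = NULL, y_val = NULL,
                    seed_offset = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + seed_offset)
  n <- dim(x)[1]; C <- dim(x)[2]; L <- dim(x)[3]
  net <- cnn_init(arch, C, L)
  state <- adam_init(net)
  t_adam <- 0L
  history <- NULL
  best <- list(f1 = -Inf, epoch = NA_integer_, net = net)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      fwd <- cnn_forward(net, xb, dropout = arch$dropout, train = TRUE)
      grads <- cnn_backward(net, fwd, y[idx])
      t_adam <- t_adam + 1L
      upd <- adam_step(net, grads, state, cfg$lr, t_adam)
      net <- upd$net; state <- upd$state
    }
    if (!is.null(x_val)) {
      pv <- cnn_forward(net, x_val)$prob
      m <- prob_metrics(y_val, pv)
      history <- rbind(history, c(epoch = ep, m))
      if (m[["f1"]] > best$f1) {          # strict >: earliest epoch wins ties
        best <- list(f1 = m[["f1"]], epoch = ep, net = net)
      }
    }
  }
  if (is.null(x_val)) best <- list(f1 = NA_real_, epoch = cfg$epochs, net = net)
  list(net = net, best_net = best$net, best_epoch = best$epoch,
       history = as.data.frame(history))
}

cnn_predict <- function(net, x) cnn_forward(net, x)$prob
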