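# One-dimensional convolutional network base learner.
#
# Architecture (defaults): conv(16 filters, width 3, ReLU) -> max-pool(2) ->
# conv(32 filters, width 3, ReLU) -> global average pool -> dense(32, ReLU)
# -> dense(2, softmax). Convolutions are "valid" (no padding) and run over
# the length-d pair feature vector as a single input channel. Kernel widths
# clamp to the available length and pooling is skipped when the feature map
# is shorter than the pool width, so the same network handles short toy
# inputs (d >= 1) and the default d = 64.
#
# Everything is vectorized over the minibatch via im2col: a convolution
# becomes one matrix multiplication with rows indexed by (sample, output
# position), sample fastest (column-major reshape convention used
# throughout).

#' Configuration of the CNN base learner
#'
#' @param d input feature width (length of a pair feature vector).
#' @param conv_filters integer 2-vector, filters in the two conv layers.
#' @param kernel_width nominal convolution kernel width (clamped to the
#'   available map length).
#' @param pool_width max-pool width/stride after the first convolution.
#' @param dense_units hidden dense layer width.
#' @param batch_size SGD minibatch size.
#' @param sgd_lr optimizer step size (distinct from the boosting shrinkage).
#' @param momentum SGD momentum coefficient.
#' @return A list of class `cnn_config` with the derived layer geometry.
#' @export
cnn_config <- function(d, conv_filters = c(16L, 32L), kernel_width = 3L,
                       pool_width = 2L, dense_units = 32L,
                       batch_size = 32L, sgd_lr = 0.1, momentum = 0.9) {
  stopifnot(d >= 1, length(conv_filters) == 2L)
  k1 <- min(kernel_width, d)
  L1 <- d - k1 + 1L
  pooled <- L1 >= pool_width
  L1p <- if (pooled) L1 %/% pool_width else L1
  k2 <- min(kernel_width, L1p)
  L2 <- L1p - k2 + 1L
  structure(list(
    d = as.integer(d), f1 = as.integer(conv_filters[1L]),
    f2 = as.integer(conv_filters[2L]), k1 = as.integer(k1),
    k2 = as.integer(k2), L1 = as.integer(L1), L1p = as.integer(L1p),
    L2 = as.integer(L2), pooled = pooled, pool_width = as.integer(pool_width),
    h = as.integer(dense_units), batch_size = as.integer(batch_size),
    sgd_lr = sgd_lr, momentum = momentum
  ), class = "cnn_config")
}

# He-style initialization, deterministic in `seed`.
cnn_init <- function(cfg, seed) {
  set.seed(derive_seed(seed, 11L))
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  list(
    W1 = he(cfg$k1, cfg$f1),            b1 = numeric(cfg$f1),
    W2 = he(cfg$k2 * cfg$f1, cfg$f2),   b2 = numeric(cfg$f2),
    W3 = he(cfg$f2, cfg$h),             b3 = numeric(cfg$h),
    W4 = he(cfg$h, 2L),                 b4 = numeric(2L)
  )
}

# im2col for a (B x len) map with `ch` channels stored as an array reshaped
# to (B*len) x ch; returns (B*Lout) x (k*ch).
im2col1 <- function(X, k, Lout) {
  B <- nrow(X)
  out <- matrix(0, B * Lout, k)
  for (t in seq_len(k)) out[, t] <- as.vector(X[, t:(t + Lout - 1L)])
  out
}

cnn_forward <- function(params, X, cfg, keep = FALSE) {
  B <- nrow(X)
  Xc1 <- im2col1(X, cfg$k1, cfg$L1)
  H1 <- sweep(Xc1 %*% params$W1, 2L, params$b1, `+`)
  A1 <- H1 * (H1 > 0)
  A1arr <- A1; dim(A1arr) <- c(B, cfg$L1, cfg$f1)
  if (cfg$pooled) {
    o1 <- seq.int(1L, cfg$L1p * 2L, by = 2L)
    a <- A1arr[, o1, , drop = FALSE]
    b <- A1arr[, o1 + 1L, , drop = FALSE]
    M1 <- a >= b                      # ties route gradient to the first slot
    P <- pmax(a, b)
  } else {
    M1 <- NULL
    P <- A1arr
  }
  # conv2 im2col: tap blocks of k2 consecutive pooled positions, all channels
  Xc2 <- matrix(0, B * cfg$L2, cfg$k2 * cfg$f1)
  for (t in seq_len(cfg$k2)) {
    S <- P[, t:(t + cfg$L2 - 1L), , drop = FALSE]
    dim(S) <- c(B * cfg$L2, cfg$f1)
    Xc2[, ((t - 1L) * cfg$f1 + 1L):(t * cfg$f1)] <- S
  }
  H2 <- sweep(Xc2 %*% params$W2, 2L, params$b2, `+`)
  A2 <- H2 * (H2 > 0)
  A2g <- A2; dim(A2g) <- c(B, cfg$L2 * cfg$f2)
  G <- A2g %*% kronecker(diag(cfg$f2), matrix(1 / cfg$L2, cfg$L2, 1L))
  HD <- sweep(G %*% params$W3, 2L, params$b3, `+`)
  D1 <- HD * (HD > 0)
  logits <- sweep(D1 %*% params$W4, 2L, params$b4, `+`)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  if (!keep) return(probs)
  list(probs = probs, Xc1 = Xc1, H1 = H1, M1 = M1, P = P, Xc2 = Xc2,
       H2 = H2, G = G, D1 = D1, B = B)
}

# Gradients of the weighted cross-entropy loss
#   L = (1/B) sum_i coef_i * CE(probs_i, y_i)
# for one minibatch; `coef` are per-sample loss multipliers (boosting
# sample weights rescaled so the uniform case equals 1).
cnn_gradients <- function(params, fw, y, coef, cfg) {
  B <- fw$B
  T2 <- matrix(c(y, 1 - y), ncol = 2L)   # column 1 = association class
  dlog <- (fw$probs - T2) * (coef / B)
  g <- list()
  g$W4 <- crossprod(fw$D1, dlog); g$b4 <- colSums(dlog)
  dD1 <- dlog %*% t(params$W4); dD1 <- dD1 * (fw$D1 > 0)
  g$W3 <- crossprod(fw$G, dD1); g$b3 <- colSums(dD1)
  dG <- dD1 %*% t(params$W3)
  dA2 <- dG[rep(seq_len(B), cfg$L2), , drop = FALSE] / cfg$L2
  dH2 <- dA2 * (fw$H2 > 0)
  g$W2 <- crossprod(fw$Xc2, dH2); g$b2 <- colSums(dH2)
  dXc2 <- dH2 %*% t(params$W2)
  dP <- array(0, c(B, cfg$L1p, cfg$f1))
  for (t in seq_len(cfg$k2)) {
    blk <- dXc2[, ((t - 1L) * cfg$f1 + 1L):(t * cfg$f1), drop = FALSE]
    dim(blk) <- c(B, cfg$L2, cfg$f1)
    dP[, t:(t + cfg$L2 - 1L), ] <- dP[, t:(t + cfg$L2 - 1L), , drop = FALSE] + blk
  }
  if (cfg$pooled) {
    dA1arr <- array(0, c(B, cfg$L1, cfg$f1))
    o1 <- seq.int(1L, cfg$L1p * 2L, by = 2L)
    dA1arr[, o1, ] <- dP * fw$M1
    dA1arr[, o1 + 1L, ] <- dP * !fw$M1
  } else {
    dA1arr <- dP
  }
  dA1 <- dA1arr; dim(dA1) <- c(B * cfg$L1, cfg$f1)
  dH1 <- dA1 * (fw$H1 > 0)
  g$W1 <- crossprod(fw$Xc1, dH1); g$b1 <- colSums(dH1)
  g
}

# One SGD-with-momentum step on a minibatch.
cnn_backward_step <- function(params, vel, fw, y, coef, cfg) {
  g <- cnn_gradients(params, fw, y, coef, cfg)
  for (nm in names(g)) {
    vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$sgd_lr * g[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

# Weighted cross-entropy loss matching cnn_gradients (for gradient checks).
cnn_loss <- function(params, X, y, coef, cfg) {
  probs <- pmax(cnn_forward(params, X, cfg), 1e-300)
  ce <- -ifelse(y == 1, log(probs[, 1L]), log(probs[, 2L]))
  sum(coef * ce) / nrow(X)
}

# Fit one CNN by minibatch SGD on weighted cross-entropy. `weights` are the
# boosting sample weights (sum 1 over the dataset); they enter the loss as
# per-sample multipliers scaled by p so uniform weights reduce to the plain
# unweighted loss. `init_params` enables transfer learning across boosting
# rounds: when supplied, training continues from those parameters.
train_cnn <- function(X, y, weights = NULL, cfg, epochs, seed,
                      init_params = NULL) {
  p <- nrow(X)
  if (is.null(weights)) weights <- rep(1 / p, p)
  coef_all <- weights * p
  params <- if (is.null(init_params)) cnn_init(cfg, seed) else init_params
  vel <- lapply(params, function(w) w * 0)
  set.seed(derive_seed(seed, 23L))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(p)
    starts <- seq.int(1L, p, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, p)]
      Xb <- X[idx, , drop = FALSE]
      fw <- cnn_forward(params, Xb, cfg, keep = TRUE)
      upd <- cnn_backward_step(params, vel, fw, y[idx], coef_all[idx], cfg)
      params <- upd$params; vel <- upd$vel
    }
  }
  structure(list(params = params, cfg = cfg, epochs = epochs, seed = seed),
            class = "cnn_estimator")
}

# Class probabilities (column 1 = association, column 2 = non-association).
cnn_probs <- function(est, X) {
  if (ncol(X) != est$cfg$d)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(X), est$cfg$d))
  cnn_forward(est$params, X, est$cfg, keep = FALSE)
}
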