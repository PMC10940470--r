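# Real (SAMME.R) AdaBoost over CNN base estimators with transfer learning:
# each boosting round's CNN starts from the previous round's trained
# parameters instead of a fresh initialization, so later rounds fine-tune
# on the re-weighted sample distribution.

PROB_FLOOR <- 1e-12

#' Initialize boosting sample weights
#'
#' Returns the uniform importance vector `D` with every entry exactly
#' `1/p`, the starting distribution of the boosting loop.
#'
#' @param p number of training samples.
#' @return Numeric vector of length `p` summing to 1.
#' @export
init_sample_weights <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("p must be a positive integer")
  rep(1 / p, as.integer(p))
}

#' Train the boosted CNN ensemble
#'
#' Fits `Q` CNN base estimators sequentially. Round `q` trains on the data
#' with per-sample loss multipliers proportional to the current weight
#' vector `D`; afterwards `D` is updated by the two-class SAMME.R rule
#' \deqn{D_i \leftarrow D_i \exp\{-\nu \tfrac{K-1}{K}\, \tilde y_i^T \log
#' p_q(x_i)\}, \quad K = 2,}
#' where \eqn{\tilde y_i} is the +1 / -1 class coding, \eqn{\nu} the
#' boosting learning rate, and probabilities are floored at 1e-12 before
#' logs; `D` is then renormalized to sum 1. Round `q+1`'s CNN is
#' initialized from round `q`'s trained parameters (transfer learning).
#'
#' @param ds a `labeled_dataset` with features attached, or a list with
#'   elements `X` (p x d matrix) and `y` (0/1 labels).
#' @param Q number of boosting rounds (paper default 100; tests use a
#'   reduced profile).
#' @param epochs SGD epochs per round (paper default 10).
#' @param learning_rate boosting shrinkage applied to the weight update
#'   (paper default 0.1).
#' @param seed integer; drives parameter initialization and minibatch order.
#' @param cnn a [cnn_config()]; default geometry is derived from `ncol(X)`.
#' @return Object of class `boosted_cnn`: list of `Q` estimators, the final
#'   weight vector `D`, and per-round weighted error summaries.
#' @export
train_boosted_cnn <- function(ds, Q = 100L, epochs = 10L, learning_rate = 0.1,
                              seed = 1L, cnn = NULL) {
  X <- ds$X; y <- as.numeric(ds$y)
  if (is.null(X)) stop("dataset has no feature matrix")
  if (!all(is.finite(X))) stop("non-finite features")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (Q < 1L || epochs < 1L) stop("Q and epochs must be >= 1")
  p <- nrow(X)
  cfg <- if (is.null(cnn)) cnn_config(ncol(X)) else cnn
  D <- init_sample_weights(p)
  estimators <- vector("list", Q)
  round_log <- data.frame(round = seq_len(Q), weighted_error = NA_real_)
  D_history <- vector("list", Q + 1L)
  D_history[[1L]] <- D
  miss_history <- vector("list", Q)
  prev <- NULL
  for (q in seq_len(Q)) {
    est <- train_cnn(X, y, weights = D, cfg = cfg, epochs = epochs,
                     seed = derive_seed(seed, q), init_params = prev)
    probs <- pmax(cnn_probs(est, X), PROB_FLOOR)
    # +1/-1 coding: ytilde^T log p = log p_true - log p_other  (K = 2)
    margin <- ifelse(y == 1, log(probs[, 1L]) - log(probs[, 2L]),
                     log(probs[, 2L]) - log(probs[, 1L]))
    miss <- which((probs[, 1L] > probs[, 2L]) != (y == 1))
    round_log$weighted_error[q] <- sum(D[miss])
    D <- D * exp(-learning_rate * 0.5 * margin)
    D <- D / sum(D)
    stopifnot(abs(sum(D) - 1) < 1e-9)
    estimators[[q]] <- est
    D_history[[q + 1L]] <- D
    miss_history[[q]] <- miss
    prev <- est$params
  }
  structure(list(estimators = estimators, Q = as.integer(Q), D = D,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 cfg = cfg, seed = as.integer(seed), round_log = round_log,
                 D_history = D_history, miss_history = miss_history),
            class = "boosted_cnn")
}

#' @export
print.boosted_cnn <- function(x, ...) {
  cat(sprintf("Boosted CNN ensemble: Q = %d rounds, %d epochs/round, shrinkage %.3g\n",
              x$Q, x$epochs, x$learning_rate))
  invisible(x)
}

# Symmetric log-odds contribution of one estimator's probabilities:
# c_k = log o_k - (1/2) sum_k' log o_k', floored before logs.
samme_contrib <- function(probs) {
  lp <- log(pmax(probs, PROB_FLOOR))
  lp - rowMeans(lp)
}

#' Score samples with the boosted CNN ensemble
#'
#' Aggregates the `Q` estimators by the real-boosting rule: each
#' estimator's class probabilities \eqn{o^q_k} are mapped to symmetric
#' log-odds \eqn{c^q_k = \log o^q_k - \tfrac12 \sum_{k'} \log o^q_{k'}}
#' and summed over rounds. The hard label is the argmax over classes
#' (ties resolve to non-association); the continuous association score is
#' the class-1 component of a softmax over the two aggregated sums.
#'
#' @param model a [train_boosted_cnn()] fit.
#' @param X feature matrix with the training feature width.
#' @return List with `score` (association score in `[0,1]`), `label`
#'   (0/1 hard labels) and `agg` (the two aggregated log-odds columns).
#' @export
boosted_cnn_scores <- function(model, X) {
  agg <- matrix(0, nrow(X), 2L)
  for (est in model$estimators)
    agg <- agg + samme_contrib(cnn_probs(est, X))
  label <- as.integer(agg[, 1L] > agg[, 2L])  # tie -> non-association
  z <- agg - apply(agg, 1L, max)
  ez <- exp(z)
  list(score = ez[, 1L] / rowSums(ez), label = label, agg = agg)
}
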