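# Discrete AdaBoost with decision stumps, used as the classical boosting
# baseline in the ablation sweep. Each round fits the weighted-error-optimal
# single-feature threshold rule and reweights samples by the standard
# exponential rule; scores are a logistic transform of the additive margin.

# Best stump on weighted data. Polarity +1 predicts class 1 when
# x > threshold; polarity -1 the reverse. Returns the weighted-error
# minimizer over all features, distinct-value cuts and both polarities.
fit_stump <- function(X, y, w) {
  p <- nrow(X)
  best <- list(err = Inf, feature = 1L, threshold = -Inf, polarity = 1)
  W1 <- sum(w[y == 1])
  W0 <- sum(w[y == 0])
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j], method = "radix")
    xv <- X[ord, j]
    w1l <- cumsum(w[ord] * (y[ord] == 1))
    w0l <- cumsum(w[ord] * (y[ord] == 0))
    cuts <- c(0L, which(diff(xv) > 0))         # cut after these positions
    W1L <- c(0, w1l)[cuts + 1L]
    W0L <- c(0, w0l)[cuts + 1L]
    err_pos <- W1L + (W0 - W0L)                # class1 left or class0 right
    err_neg <- (W1 + W0) - err_pos
    thr <- ifelse(cuts == 0L, -Inf, (xv[pmax(cuts, 1L)] +
                                       xv[pmin(cuts + 1L, p)]) / 2)
    k <- which.min(pmin(err_pos, err_neg))
    e <- min(err_pos[k], err_neg[k])
    if (e < best$err) {
      best <- list(err = e, feature = j, threshold = thr[k],
                   polarity = if (err_pos[k] <= err_neg[k]) 1 else -1)
    }
  }
  best
}

stump_predict <- function(st, X) {
  h <- ifelse(X[, st$feature] > st$threshold, 1L, 0L)
  if (st$polarity < 0) h <- 1L - h
  h
}

#' Discrete AdaBoost of decision stumps
#'
#' Classical AdaBoost baseline on the same pair features, used by the
#' ablation harness. Stump base learners, exponential reweighting, additive
#' margin scored through a logistic link.
#'
#' @param ds a `labeled_dataset` with features, or list with `X`, `y`.
#' @param n_estimators boosting rounds.
#' @param learning_rate shrinkage on the stump vote weights.
#' @param seed integer (used only to break degenerate early stops
#'   deterministically; the fit itself is deterministic).
#' @return Object of class `adaboost_stump`.
#' @export
train_adaboost_stump <- function(ds, n_estimators = 100L, learning_rate = 0.1,
                                 seed = 1L) {
  X <- ds$X; y <- as.integer(ds$y)
  if (is.null(X)) stop("dataset has no feature matrix")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  p <- nrow(X)
  w <- init_sample_weights(p)
  stumps <- list()
  votes <- numeric(0)
  for (t in seq_len(n_estimators)) {
    st <- fit_stump(X, y, w)
    err <- max(st$err, 1e-12)
    if (err >= 0.5) break                       # no better than chance
    a <- learning_rate * log((1 - err) / err)
    h <- stump_predict(st, X)
    w <- w * exp(a * (h != y))
    w <- w / sum(w)
    stumps[[t]] <- st
    votes[t] <- a
    if (st$err < 1e-12) break                   # perfect stump, margin fixed
  }
  structure(list(stumps = stumps, votes = votes, d = ncol(X)),
            class = "adaboost_stump")
}

# Association score: logistic of the signed additive margin.
adaboost_stump_scores <- function(model, X) {
  if (ncol(X) != model$d) stop("feature width mismatch")
  margin <- numeric(nrow(X))
  for (t in seq_along(model$stumps)) {
    h <- stump_predict(model$stumps[[t]], X)
    margin <- margin + model$votes[t] * ifelse(h == 1L, 1, -1)
  }
  1 / (1 + exp(-2 * margin))
}
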