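# Gradient-boosted decision-tree head. The boosting algorithm itself
# (split finding by variance gain, additive tree model) is delegated to
# xgboost; this module wraps it behind the pair-classifier surface and
# implements the convex score fusion with the boosted-CNN head.

#' Train the gradient-boosted tree head
#'
#' Fits a binary gradient-boosted decision-tree classifier on the pair
#' features, emitting association probabilities in `[0, 1]`. Defaults
#' follow the study settings: 100 trees, shrinkage 0.1.
#'
#' @param ds a `labeled_dataset` with features, or list with `X`, `y`.
#' @param n_estimators number of boosting rounds (trees).
#' @param learning_rate shrinkage per round.
#' @param seed integer seed (single-threaded training keeps the fit
#'   deterministic).
#' @param ... passthrough parameters for the underlying tree booster
#'   (e.g. `max_depth`).
#' @return Object of class `gbm_head` wrapping the booster handle.
#' @export
train_gbm <- function(ds, n_estimators = 100L, learning_rate = 0.1,
                      seed = 1L, ...) {
  X <- ds$X; y <- as.numeric(ds$y)
  if (is.null(X)) stop("dataset has no feature matrix")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (n_estimators < 1L) stop("n_estimators must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  booster <- xgboost::xgboost(
    x = X, y = factor(y, levels = c(0, 1)),
    objective = "binary:logistic", nrounds = as.integer(n_estimators),
    learning_rate = learning_rate, nthreads = 1L,
    seed = derive_seed(seed, 31L), verbosity = 0L, ...
  )
  structure(list(booster = booster, d = ncol(X),
                 n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate),
            class = "gbm_head")
}

#' @export
print.gbm_head <- function(x, ...) {
  cat(sprintf("Gradient-boosted tree head: %d trees, shrinkage %.3g\n",
              x$n_estimators, x$learning_rate))
  invisible(x)
}

# Association probabilities from the tree head.
gbm_scores <- function(model, X) {
  if (ncol(X) != model$d)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(X), model$d))
  as.numeric(predict(model$booster, X))
}

#' Convex fusion of the two head scores
#'
#' Elementwise \eqn{P(x) = \alpha C(x) + (1 - \alpha) F(x)} where `C` is
#' the boosted-CNN association score and `F` the tree-head probability.
#' The weight on the tree head is always `1 - alpha`.
#'
#' @param c_scores boosted-CNN scores in `[0, 1]`.
#' @param f_scores tree-head scores in `[0, 1]`, same length.
#' @param alpha fusion weight in `[0, 1]` (study default 0.4).
#' @return Fused score vector in `[0, 1]`.
#' @export
fuse_scores <- function(c_scores, f_scores, alpha = 0.4) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (length(c_scores) != length(f_scores))
    stop("score vectors must have equal length")
  alpha * c_scores + (1 - alpha) * f_scores
}

# Reference single-split variance gain in the one-side-sampling form:
# large-|gradient| samples A are kept, a fraction of the rest is subsampled
# into B and reweighted by (1-a)/b. Kept as a documented reference for the
# split criterion the delegated tree booster optimizes; not used in training.
goss_variance_gain <- function(x, g, split, A, B, a_frac, b_frac) {
  n <- length(x)
  wsum <- function(idx, side) {
    keep <- idx[side(x[idx])]
    sum(g[keep])
  }
  left <- function(v) v <= split
  right <- function(v) v > split
  nl <- sum(x <= split); nr <- n - nl
  gl <- wsum(A, left) + (1 - a_frac) / b_frac * wsum(B, left)
  gr <- wsum(A, right) + (1 - a_frac) / b_frac * wsum(B, right)
  (gl^2 / nl + gr^2 / nr) / n
}
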