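#' Train the fused two-head ensemble on a labeled dataset
#'
#' Fits the boosted-CNN head and the gradient-boosted tree head on the same
#' samples (with child seeds derived from `seed`) and stores the convex
#' fusion weight. Ensemble scores are
#' \eqn{P(x) = \alpha C(x) + (1-\alpha) F(x)}.
#'
#' @param ds a `labeled_dataset` with features attached.
#' @param cnn list of boosted-CNN settings: `Q`, `epochs`, `learning_rate`,
#'   plus optional [cnn_config()] fields (`batch_size`, `sgd_lr`, ...).
#' @param gbm list of tree-head settings: `n_estimators`, `learning_rate`.
#' @param alpha fusion weight on the boosted-CNN head (default 0.4).
#' @param seed master seed.
#' @return Object of class `ensemble_model`.
#' @export
train_ensemble <- function(ds, cnn = list(), gbm = list(), alpha = 0.4,
                           seed = 1L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  cnn <- utils::modifyList(
    list(Q = 100L, epochs = 10L, learning_rate = 0.1,
         batch_size = 32L, sgd_lr = 0.1, momentum = 0.9), cnn)
  gbm <- utils::modifyList(
    list(n_estimators = 100L, learning_rate = 0.1), gbm)
  cfg <- cnn_config(ncol(ds$X), batch_size = cnn$batch_size,
                    sgd_lr = cnn$sgd_lr, momentum = cnn$momentum)
  bcnn <- train_boosted_cnn(ds, Q = cnn$Q, epochs = cnn$epochs,
                            learning_rate = cnn$learning_rate,
                            seed = derive_seed(seed, 201L), cnn = cfg)
  head_gbm <- train_gbm(ds, n_estimators = gbm$n_estimators,
                        learning_rate = gbm$learning_rate,
                        seed = derive_seed(seed, 202L))
  structure(list(boosted_cnn = bcnn, gbm = head_gbm,
                 alpha = alpha, beta = 1 - alpha, seed = as.integer(seed)),
            class = "ensemble_model")
}

# Score a feature matrix with both heads and fuse.
ensemble_scores <- function(model, X) {
  cs <- boosted_cnn_scores(model$boosted_cnn, X)$score
  fs <- gbm_scores(model$gbm, X)
  data.frame(c_score = cs, f_score = fs,
             fused_score = fuse_scores(cs, fs, model$alpha))
}

#' Fit the boosted lncRNA-disease association model
#'
#' The main fitting function. From a binary association matrix it (1)
#' extracts pair features by truncated SVD (rank `e`, concatenated lncRNA
#' and disease embeddings, `d = 2e`), (2) assembles a training set of all
#' positive pairs plus sampled negatives, and (3) trains the fused ensemble:
#' a transfer-learning SAMME.R AdaBoost of 1-D CNNs and a gradient-boosted
#' tree head, combined as \eqn{\alpha C(x) + (1-\alpha) F(x)}.
#'
#' @param x an [assoc_matrix()], a path to an edge-list file, or a
#'   two-column data frame of (lncRNA_id, disease_id) edges.
#' @param e truncation rank (default 32, giving the study's d = 64).
#' @param scaling feature scaling, `"sqrt_sigma"` (default) or `"raw"`.
#' @param mode negative sampling mode, `"balanced"` (default) or
#'   `"all_pairs"`.
#' @param neg_ratio negatives per positive in balanced mode.
#' @param alpha fusion weight on the boosted-CNN head.
#' @param cnn,gbm head settings, see [train_ensemble()]. The study defaults
#'   are `Q = 100`, `epochs = 10`, shrinkage 0.1 for the boosted CNN and 100
#'   trees, shrinkage 0.1 for the tree head.
#' @param seed master seed for sampling and training.
#' @return Object of class `ldaboost`: the association matrix, the
#'   factorization, the training dataset, and the fitted `ensemble_model`.
#' @examples
#' am <- simulate_association_matrix(synthetic_spec(30, 40, r = 2, seed = 3))$am
#' fit <- ldaboost(am, e = 4, cnn = list(Q = 2, epochs = 2), seed = 3)
#' head(predict(fit))
#' @export
ldaboost <- function(x, e = 32L, scaling = c("sqrt_sigma", "raw"),
                     mode = c("balanced", "all_pairs"), neg_ratio = 1,
                     alpha = 0.4, cnn = list(), gbm = list(), seed = 1L) {
  scaling <- match.arg(scaling)
  mode <- match.arg(mode)
  am <- if (inherits(x, "assoc_matrix")) x else
    if (is.character(x)) load_association_edges(x) else
      edges_to_matrix(x)
  f <- svd_factorize(am, e)
  ds <- assemble_dataset(am, features = f, mode = mode,
                         neg_ratio = neg_ratio,
                         seed = derive_seed(seed, 301L), scaling = scaling)
  model <- train_ensemble(ds, cnn = cnn, gbm = gbm, alpha = alpha,
                          seed = derive_seed(seed, 302L))
  structure(list(am = am, factorization = f, scaling = scaling,
                 dataset = ds, model = model, e = as.integer(e),
                 alpha = alpha, seed = as.integer(seed),
                 call = match.call()),
            class = "ldaboost")
}

# Edge data frame -> assoc_matrix (first-appearance ordering).
edges_to_matrix <- function(df) {
  df <- as.data.frame(df)
  if (ncol(df) < 2L) stop("edge data frame needs two columns")
  lnc <- as.character(df[[1L]]); dis <- as.character(df[[2L]])
  lnc_ids <- unique(lnc); dis_ids <- unique(dis)
  Y <- matrix(0L, length(lnc_ids), length(dis_ids),
              dimnames = list(lnc_ids, dis_ids))
  Y[cbind(match(lnc, lnc_ids), match(dis, dis_ids))] <- 1L
  assoc_matrix(Y, lnc_ids, dis_ids)
}

#' @export
print.ldaboost <- function(x, ...) {
  cat("Boosted lncRNA-disease association model\n")
  cat(sprintf("  matrix: %d lncRNAs x %d diseases, %d associations\n",
              nrow(x$am), ncol(x$am), sum(x$am)))
  cat(sprintf("  features: truncated SVD rank e = %d (d = %d, %s scaling)\n",
              x$e, 2L * x$e, x$scaling))
  cat(sprintf("  heads: boosted CNN (Q = %d) + %d-tree GBDT, fusion alpha = %.2f\n",
              x$model$boosted_cnn$Q, x$model$gbm$n_estimators, x$alpha))
  invisible(x)
}

#' @export
summary.ldaboost <- function(object, ...) {
  sc <- ensemble_scores(object$model, object$dataset$X)
  y <- object$dataset$y
  rep <- compute_metrics(y, sc$fused_score)
  out <- list(fit = object, training_metrics = rep,
              final_weights_range = range(object$model$boosted_cnn$D))
  class(out) <- "summary.ldaboost"
  out
}

#' @export
print.summary.ldaboost <- function(x, ...) {
  print(x$fit)
  cat("Training-set (resubstitution) metrics:\n")
  m <- x$training_metrics
  cat(sprintf("  precision %.4f  recall %.4f  accuracy %.4f  F1 %.4f  AUC %.4f  AUPR %.4f\n",
              m$precision, m$recall, m$accuracy, m$f1, m$auc, m$aupr))
  invisible(x)
}

#' Score lncRNA-disease pairs with a fitted model
#'
#' @param object an [ldaboost()] fit.
#' @param pairs optional two-column matrix/data frame of (lncRNA, disease)
#'   indices or identifiers; defaults to every cell of the association
#'   matrix.
#' @param ... unused.
#' @return Data frame with identifiers, the known label, both head scores
#'   and the fused association score.
#' @export
predict.ldaboost <- function(object, pairs = NULL, ...) {
  am <- object$am
  if (is.null(pairs)) {
    pairs <- cbind(rep(seq_len(nrow(am)), ncol(am)),
                   rep(seq_len(ncol(am)), each = nrow(am)))
  } else {
    pairs <- as.matrix(pairs)
    if (!is.numeric(pairs)) {
      pairs <- cbind(match(pairs[, 1L], rownames(am)),
                     match(pairs[, 2L], colnames(am)))
      if (anyNA(pairs)) stop("unknown lncRNA or disease identifier in pairs")
    }
    storage.mode(pairs) <- "integer"
  }
  X <- pair_feature_matrix(object$factorization, pairs,
                           scaling = object$scaling)
  sc <- ensemble_scores(object$model, X)
  data.frame(
    lncRNA_id = rownames(am)[pairs[, 1L]],
    disease_id = colnames(am)[pairs[, 2L]],
    label = as.integer(unclass(am)[pairs]),
    sc,
    stringsAsFactors = FALSE
  )
}

#' Rank candidate lncRNAs for a disease
#'
#' Scores every lncRNA with no observed association to the given disease
#' and returns the top `k` by fused association score (descending; ties
#' broken by lncRNA index order). Known associated lncRNAs are excluded.
#'
#' @param model an [ldaboost()] fit.
#' @param disease_id disease identifier present in the association matrix.
#' @param k number of candidates (study default 15).
#' @return Data frame of class `ranked_candidates` with `rank`,
#'   `lncRNA_id` and `fused_score`, at most `k` rows.
#' @export
rank_candidates <- function(model, disease_id, k = 15L) {
  am <- model$am
  j <- match(as.character(disease_id), colnames(am))
  if (is.na(j)) stop("unknown disease identifier: ", disease_id)
  free <- which(unclass(am)[, j] == 0L)
  if (length(free) == 0L)
    return(structure(data.frame(rank = integer(), lncRNA_id = character(),
                                fused_score = numeric()),
                     class = c("ranked_candidates", "data.frame"),
                     disease_id = as.character(disease_id), k = as.integer(k)))
  pairs <- cbind(free, rep(j, length(free)))
  X <- pair_feature_matrix(model$factorization, pairs, scaling = model$scaling)
  sc <- ensemble_scores(model$model, X)
  ord <- order(-sc$fused_score, free)
  top <- ord[seq_len(min(k, length(ord)))]
  structure(
    data.frame(rank = seq_along(top), lncRNA_id = rownames(am)[free[top]],
               fused_score = sc$fused_score[top], stringsAsFactors = FALSE),
    class = c("ranked_candidates", "data.frame"),
    disease_id = as.character(disease_id), k = as.integer(k)
  )
}

#' @export
print.ranked_candidates <- function(x, ...) {
  cat(sprintf("Top %d candidate lncRNAs for disease '%s' (no observed association):\n",
              nrow(x), attr(x, "disease_id")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
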