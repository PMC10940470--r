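#' Classification and ranking metrics for pair scores
#'
#' Computes the six study metrics. Precision, recall, accuracy and F1 come
#' from the confusion matrix at `score >= threshold`. AUC is the
#' probability that a random positive outscores a random negative, ties
#' counting one half (Wilcoxon form). AUPR is the area under the
#' precision-recall curve by the step-interpolation rule (average
#' precision), with samples ranked by descending score and ties broken by
#' input order for bit-reproducibility.
#'
#' @param y_true 0/1 label vector.
#' @param scores numeric scores in `[0, 1]`, same length.
#' @param threshold decision threshold for the four thresholded metrics.
#' @return Object of class `metrics_report`: list with `precision`,
#'   `recall`, `accuracy`, `f1`, `auc`, `aupr`, `threshold`. If `y_true`
#'   has a single class, AUC and AUPR are `NA` with a warning and the
#'   thresholded metrics are still returned.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  accuracy <- (tp + tn) / length(y)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("single-class labels: AUC and AUPR undefined")
    auc <- aupr <- NA_real_
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
    ord <- order(-scores, seq_along(scores))
    tp_cum <- cumsum(y[ord] == 1L)
    prec_at_k <- tp_cum / seq_along(ord)
    rec_at_k <- tp_cum / npos
    aupr <- sum(diff(c(0, rec_at_k)) * prec_at_k)
  }
  structure(list(precision = precision, recall = recall, accuracy = accuracy,
                 f1 = f1, auc = auc, aupr = aupr, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  accuracy %.4f  F1 %.4f  AUC %.4f  AUPR %.4f (threshold %.2f)\n",
              x$precision, x$recall, x$accuracy, x$f1, x$auc, x$aupr,
              x$threshold))
  invisible(x)
}

METRIC_NAMES <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")

#' Build a cold-start cross-validation fold plan
#'
#' Three protocols: `"lncrna"` partitions lncRNAs into `k` folds (a fold's
#' test set is every pair whose lncRNA is held out: new-lncRNA cold start);
#' `"disease"` is the symmetric column protocol; `"pair"` partitions a
#' balanced sample of pairs (all positives plus `neg_ratio` sampled
#' negatives per positive) directly. Fold sizes differ by at most one and
#' the partition is deterministic in `seed`.
#'
#' @param am an [assoc_matrix()].
#' @param mode `"lncrna"`, `"disease"` or `"pair"`.
#' @param k number of folds (study protocol: 5).
#' @param seed integer seed.
#' @param neg_ratio negatives per positive when sampling pairs (pair mode).
#' @return Object of class `fold_plan`: `mode`, `k`, `folds` (list of `k`
#'   disjoint index vectors covering the entity or pair set), and for pair
#'   mode the sampled `pairs` matrix and their `labels`.
#' @export
make_folds <- function(am, mode = c("lncrna", "disease", "pair"), k = 5L,
                       seed = 1L, neg_ratio = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || k < 2L) stop("k must be at least 2")
  k <- as.integer(k)
  pairs <- NULL; labels <- NULL
  if (mode == "pair") {
    ds <- assemble_dataset(am, features = NULL, mode = "balanced",
                           neg_ratio = neg_ratio,
                           seed = derive_seed(seed, 401L))
    pairs <- ds$pairs; labels <- ds$y
    n_units <- nrow(pairs)
  } else {
    n_units <- if (mode == "lncrna") nrow(am) else ncol(am)
  }
  if (k > n_units)
    stop(sprintf("k = %d exceeds the number of %ss to split (%d)",
                 k, mode, n_units))
  set.seed(derive_seed(seed, 402L))
  perm <- sample.int(n_units)
  sizes <- rep(n_units %/% k, k)
  extra <- n_units %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(perm, rep(seq_len(k), times = sizes))
  names(folds) <- NULL
  structure(list(mode = mode, k = k, folds = folds, seed = as.integer(seed),
                 pairs = pairs, labels = labels, neg_ratio = neg_ratio),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("%d-fold cold-start plan on %ss: fold sizes [%s]\n",
              x$k, x$mode, paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

# Positive and sampled-negative pairs restricted to one side of an entity
# split (rows for the lncRNA protocol, columns for the disease protocol).
side_pairs <- function(am, mode, entities, neg_ratio, seed) {
  Y <- unclass(am)
  n <- nrow(Y)
  if (mode == "lncrna") {
    sub <- Y[entities, , drop = FALSE]
    cells <- which(sub == 1L)
    rows <- entities[(cells - 1L) %% length(entities) + 1L]
    cols <- (cells - 1L) %/% length(entities) + 1L
    zero <- which(sub == 0L)
    zrows <- entities[(zero - 1L) %% length(entities) + 1L]
    zcols <- (zero - 1L) %/% length(entities) + 1L
  } else {
    sub <- Y[, entities, drop = FALSE]
    cells <- which(sub == 1L)
    rows <- (cells - 1L) %% n + 1L
    cols <- entities[(cells - 1L) %/% n + 1L]
    zero <- which(sub == 0L)
    zrows <- (zero - 1L) %% n + 1L
    zcols <- entities[(zero - 1L) %/% n + 1L]
  }
  n_pos <- length(rows)
  if (n_pos == 0L) return(NULL)
  n_neg <- min(floor(neg_ratio * n_pos), length(zero))
  set.seed(seed)
  pick <- sample.int(length(zero), n_neg)
  pairs <- rbind(cbind(rows, cols), cbind(zrows[pick], zcols[pick]))
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  set.seed(seed + 1L)
  ord <- sample.int(length(y))
  list(pairs = pairs[ord, , drop = FALSE], y = y[ord])
}

# Assemble one fold's train/test feature sets under the chosen masking
# policy. Returns NULL (with a warning) when the fold is unusable.
fold_data <- function(am, plan, f, config) {
  mask <- config$mask
  seed_f <- derive_seed(config$seed, 500L + f)
  if (plan$mode == "pair") {
    te <- plan$folds[[f]]
    tr <- setdiff(seq_len(nrow(plan$pairs)), te)
    ytr <- plan$labels[tr]; yte <- plan$labels[te]
    if (sum(yte == 1L) == 0L) {
      warning(sprintf("fold %d skipped: no positives on the test side", f))
      return(NULL)
    }
    Ymask <- if (isTRUE(mask)) {
      mask_cells(am, plan$pairs[te[yte == 1L], , drop = FALSE])
    } else unclass(am)
    if (all(Ymask == 0)) {
      warning(sprintf("fold %d skipped: masking left no associations", f))
      return(NULL)
    }
    fct <- svd_factorize(Ymask, config$e)
    list(Xtr = pair_feature_matrix(fct, plan$pairs[tr, , drop = FALSE],
                                   config$scaling),
         ytr = ytr,
         Xte = pair_feature_matrix(fct, plan$pairs[te, , drop = FALSE],
                                   config$scaling),
         yte = yte, factorization = fct, seed = seed_f)
  } else {
    te_ent <- plan$folds[[f]]
    tr_ent <- setdiff(seq_len(if (plan$mode == "lncrna") nrow(am)
                              else ncol(am)), te_ent)
    test <- side_pairs(am, plan$mode, te_ent, config$neg_ratio,
                       derive_seed(seed_f, 1L))
    train <- side_pairs(am, plan$mode, tr_ent, config$neg_ratio,
                        derive_seed(seed_f, 2L))
    if (is.null(test)) {
      warning(sprintf("fold %d skipped: no positives on the test side", f))
      return(NULL)
    }
    if (is.null(train) || length(unique(train$y)) < 2L) {
      warning(sprintf("fold %d skipped: unusable training side", f))
      return(NULL)
    }
    Ymask <- if (isTRUE(mask)) {
      mask_cells(am, test$pairs[test$y == 1L, , drop = FALSE])
    } else unclass(am)
    fct <- svd_factorize(Ymask, config$e)
    list(Xtr = pair_feature_matrix(fct, train$pairs, config$scaling),
         ytr = train$y,
         Xte = pair_feature_matrix(fct, test$pairs, config$scaling),
         yte = test$y, factorization = fct, seed = seed_f)
  }
}

# Fill in cross-validation config defaults. Masking defaults to TRUE for
# the pair protocol (held-out positives are zeroed before factorization)
# and FALSE for entity protocols, where a fully masked held-out row or
# column would have an all-zero embedding.
cv_config <- function(config, mode) {
  defaults <- list(e = 32L, scaling = "sqrt_sigma", neg_ratio = 1,
                   alpha = 0.4, threshold = 0.5, seed = 1L,
                   cnn = list(), gbm = list(), mask = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$mask)) config$mask <- mode == "pair"
  config
}

#' Cold-start cross-validation of the full pipeline
#'
#' For each fold: optionally masks held-out positive cells, refits the
#' truncated SVD, builds train/test pair sets (test negatives drawn from
#' the test side only), trains the fused ensemble and computes the six
#' metrics on the held-out pairs. Folds whose test side has no positives
#' are skipped with a warning and excluded from aggregation.
#'
#' @param am an [assoc_matrix()].
#' @param config list of pipeline settings; recognized keys: `e`,
#'   `scaling`, `neg_ratio`, `alpha`, `threshold`, `seed`, `mask`
#'   (default: masked for the pair protocol, unmasked for entity
#'   protocols), `cnn` and `gbm` head settings.
#' @param plan a [make_folds()] plan (default: 5 folds in pair mode).
#' @return Object of class `cv_result`: per-fold metric data frame,
#'   `mean` and `sd` per metric, the plan and resolved config.
#' @export
cross_validate <- function(am, config = list(), plan = NULL) {
  if (is.null(plan))
    plan <- make_folds(am, "pair", k = 5L,
                       seed = if (is.null(config$seed)) 1L else config$seed)
  config <- cv_config(config, plan$mode)
  rows <- list(); skipped <- integer()
  for (f in seq_len(plan$k)) {
    fd <- fold_data(am, plan, f, config)
    if (is.null(fd)) { skipped <- c(skipped, f); next }
    model <- train_ensemble(list(X = fd$Xtr, y = fd$ytr),
                            cnn = config$cnn, gbm = config$gbm,
                            alpha = config$alpha, seed = fd$seed)
    sc <- ensemble_scores(model, fd$Xte)
    rep <- compute_metrics(fd$yte, sc$fused_score, config$threshold)
    rows[[length(rows) + 1L]] <-
      data.frame(fold = f, as.data.frame(rep[METRIC_NAMES]))
  }
  if (length(rows) == 0L) stop("all folds were skipped")
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[METRIC_NAMES]),
                 sd = apply(per_fold[METRIC_NAMES], 2L, stats::sd),
                 skipped = skipped, plan = plan, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cold-start CV on %ss (%d folds used%s):\n",
              x$plan$k, x$plan$mode, nrow(x$per_fold),
              if (length(x$skipped)) paste0(", skipped: ",
                                            paste(x$skipped, collapse = " "))
              else ""))
  for (m in METRIC_NAMES)
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Ablation sweep over the fusion weight and boosting variants
#'
#' Evaluates, on identical folds and with identical head fits, the fused
#' ensemble at each `alpha` in the grid alongside the single-model
#' variants: the boosted CNN alone, classical decision-stump AdaBoost on
#' the same features, and the gradient-boosted tree head alone. Heads are
#' trained once per fold and re-fused, so the comparison is controlled.
#'
#' @param am an [assoc_matrix()].
#' @param config as in [cross_validate()].
#' @param alphas fusion weight grid (study grid: 0, 0.2, 0.4, 0.6, 0.8, 1).
#' @param variants subset of `c("ensemble", "boosted_cnn", "adaboost",
#'   "gbm")`.
#' @param plan a [make_folds()] plan (default: 5 folds in pair mode).
#' @return Object of class `ablation_result`: a data frame with one row
#'   per (variant, alpha) and `mean`/`sd` columns for each metric.
#' @export
ablation_sweep <- function(am, config = list(),
                           alphas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                           variants = c("ensemble", "boosted_cnn",
                                        "adaboost", "gbm"),
                           plan = NULL) {
  if (any(alphas < 0 | alphas > 1)) stop("alphas must lie in [0, 1]")
  variants <- match.arg(variants, several.ok = TRUE)
  if (is.null(plan))
    plan <- make_folds(am, "pair", k = 5L,
                       seed = if (is.null(config$seed)) 1L else config$seed)
  config <- cv_config(config, plan$mode)
  cnn <- utils::modifyList(
    list(Q = 100L, epochs = 10L, learning_rate = 0.1,
         batch_size = 32L, sgd_lr = 0.1, momentum = 0.9), config$cnn)
  gbm <- utils::modifyList(
    list(n_estimators = 100L, learning_rate = 0.1), config$gbm)
  fold_scores <- list()
  for (f in seq_len(plan$k)) {
    fd <- fold_data(am, plan, f, config)
    if (is.null(fd)) next
    ds <- list(X = fd$Xtr, y = fd$ytr)
    cfg <- cnn_config(ncol(fd$Xtr), batch_size = cnn$batch_size,
                      sgd_lr = cnn$sgd_lr, momentum = cnn$momentum)
    bcnn <- train_boosted_cnn(ds, Q = cnn$Q, epochs = cnn$epochs,
                              learning_rate = cnn$learning_rate,
                              seed = derive_seed(fd$seed, 201L), cnn = cfg)
    gb <- train_gbm(ds, n_estimators = gbm$n_estimators,
                    learning_rate = gbm$learning_rate,
                    seed = derive_seed(fd$seed, 202L))
    ada <- if ("adaboost" %in% variants)
      train_adaboost_stump(ds, n_estimators = gbm$n_estimators,
                           learning_rate = gbm$learning_rate)
    fold_scores[[length(fold_scores) + 1L]] <- list(
      yte = fd$yte,
      c = boosted_cnn_scores(bcnn, fd$Xte)$score,
      f = gbm_scores(gb, fd$Xte),
      a = if (!is.null(ada)) adaboost_stump_scores(ada, fd$Xte)
    )
  }
  if (length(fold_scores) == 0L) stop("all folds were skipped")
  eval_rows <- function(variant, alpha, pick) {
    per <- t(vapply(fold_scores, function(fs) {
      rep <- compute_metrics(fs$yte, pick(fs), config$threshold)
      unlist(rep[METRIC_NAMES])
    }, numeric(6L)))
    data.frame(variant = variant, alpha = alpha,
               as.list(colMeans(per)),
               stats::setNames(as.list(apply(per, 2L, stats::sd)),
                               paste0(METRIC_NAMES, "_sd")))
  }
  out <- list()
  for (v in variants) {
    out[[length(out) + 1L]] <- switch(
      v,
      ensemble = do.call(rbind, lapply(alphas, function(a)
        eval_rows("ensemble", a,
                  function(fs) fuse_scores(fs$c, fs$f, a)))),
      boosted_cnn = eval_rows("boosted_cnn", NA_real_, function(fs) fs$c),
      adaboost = eval_rows("adaboost", NA_real_, function(fs) fs$a),
      gbm = eval_rows("gbm", NA_real_, function(fs) fs$f)
    )
  }
  structure(list(table = do.call(rbind, out), plan = plan, config = config,
                 alphas = alphas, n_folds_used = length(fold_scores)),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("Ablation over fusion weight and boosting variants (%d folds, %ss protocol):\n",
              x$n_folds_used, x$plan$mode))
  print.data.frame(
    cbind(x$table[, c("variant", "alpha")],
          round(x$table[METRIC_NAMES], 4)),
    row.names = FALSE)
  invisible(x)
}
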