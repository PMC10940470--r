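test_that("metrics match hand-derived values on forced examples", {
  # perfect classifier
  m <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  for (nm in ldaboost:::METRIC_NAMES) expect_equal(m[[nm]], 1)

  # hand-enumerated confusion matrix and pairwise AUC:
  # pred at 0.5 -> (1,1,1,0): TP=2, FP=1, FN=0, TN=1; positive-negative
  # score pairs: (.9,.8)+, (.9,.1)+, (.7,.8)-, (.7,.1)+ -> AUC 3/4
  m2 <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 1)
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$f1, 0.8)
  expect_equal(m2$auc, 0.75)

  # anti-classifier
  y <- rep(c(1, 0), 10)
  expect_equal(compute_metrics(y, 1 - y)$auc, 0)

  # single-class labels: thresholded metrics survive, AUC/AUPR NA
  expect_warning(m3 <- compute_metrics(c(1, 1), c(0.9, 0.2)), "single-class")
  expect_equal(m3$recall, 0.5)
  expect_true(is.na(m3$auc) && is.na(m3$aupr))
})

test_that("all six metrics match brute-force oracles to 1e-9", {
  set.seed(402)
  for (rep in 1:25) {
    n <- 60
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- round(runif(n), 2)                 # rounding forces score ties
    m <- compute_metrics(y, s)
    o <- oracle_metrics(y, s)
    for (nm in ldaboost:::METRIC_NAMES)
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(300, 1, 0.4); y[1:2] <- c(0L, 1L)
  s <- runif(300)
  expect_equal(compute_metrics(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("fold plans partition entities with near-equal sizes", {
  set.seed(12)
  am <- assoc_matrix(matrix(rbinom(10 * 7, 1, 0.4), 10, 7) |
                       (diag(1, 10, 7) == 1))
  plan <- make_folds(am, "lncrna", k = 5, seed = 2)
  expect_equal(lengths(plan$folds), rep(2L, 5))
  expect_identical(sort(unlist(plan$folds)), 1:10)

  expect_error(make_folds(assoc_matrix(matrix(1L, 2, 5)), "disease", k = 6),
               "exceeds")
  expect_error(make_folds(am, "lncrna", k = 1), "at least 2")
})

test_that("pair-mode plans carry a balanced sampled pair set", {
  am <- small_sim()$am
  plan <- make_folds(am, "pair", k = 5, seed = 3)
  expect_equal(sum(plan$labels == 1), sum(unclass(am)))
  expect_equal(sum(plan$labels == 0), sum(plan$labels == 1))
  expect_identical(sort(unlist(plan$folds)), seq_len(nrow(plan$pairs)))
  expect_lte(diff(range(lengths(plan$folds))), 1L)
})

test_that("cold-start folds keep train and test entities disjoint", {
  am <- small_sim()$am
  for (mode in c("lncrna", "disease")) {
    n_ent <- if (mode == "lncrna") nrow(am) else ncol(am)
    for (s in 1:5) {
      plan <- make_folds(am, mode, k = 5, seed = s)
      for (f in 1:5) {
        te <- plan$folds[[f]]
        tr <- setdiff(seq_len(n_ent), te)
        expect_length(intersect(te, tr), 0)
        expect_setequal(union(te, tr), seq_len(n_ent))
      }
    }
  }
})

test_that("masking removes held-out positives from the factorization", {
  am <- small_sim()$am
  pos <- which(unclass(am) == 1L)
  cells <- cbind((pos[1:10] - 1L) %% nrow(am) + 1L,
                 (pos[1:10] - 1L) %/% nrow(am) + 1L)
  Ymask <- ldaboost:::mask_cells(am, cells)
  expect_equal(sum(unclass(am)) - sum(Ymask), 10)
  f1 <- svd_factorize(Ymask, 6)
  # re-masking already-masked cells changes nothing
  f2 <- svd_factorize(ldaboost:::mask_cells(assoc_matrix(Ymask), cells), 6)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$sigma, f2$sigma)
})

test_that("cross-validation aggregates per-fold metrics consistently", {
  sim <- small_sim()
  cfg <- list(e = 6, cnn = list(Q = 2, epochs = 2),
              gbm = list(n_estimators = 30), seed = 5)
  res <- cached("cv_small",
                cross_validate(sim$am, cfg,
                               make_folds(sim$am, "pair", 3, seed = 5)))
  expect_equal(nrow(res$per_fold), 3)
  for (nm in ldaboost:::METRIC_NAMES)
    expect_equal(res$mean[[nm]], mean(res$per_fold[[nm]]))
  expect_true(all(res$per_fold$auc > 0.5))   # planted structure is learnable
})

test_that("label-shuffled data scores at chance", {
  sim <- small_sim()
  set.seed(77)
  Yshuf <- matrix(sample(as.vector(unclass(sim$am))), nrow(sim$am))
  am_null <- assoc_matrix(Yshuf)
  cfg <- list(e = 6, cnn = list(Q = 2, epochs = 2),
              gbm = list(n_estimators = 30), seed = 5)
  res <- cross_validate(am_null, cfg, make_folds(am_null, "pair", 3, seed = 5))
  expect_gt(res$mean[["auc"]], 0.35)
  expect_lt(res$mean[["auc"]], 0.65)
})

test_that("the ablation sweep is internally consistent at its endpoints", {
  sim <- small_sim()
  cfg <- list(e = 6, cnn = list(Q = 2, epochs = 2),
              gbm = list(n_estimators = 30), seed = 5)
  ab <- cached("ablation_small",
               ablation_sweep(sim$am, cfg, alphas = c(0, 0.4, 1),
                              plan = make_folds(sim$am, "pair", 3, seed = 5)))
  tab <- ab$table
  a0 <- tab[tab$variant == "ensemble" & tab$alpha == 0, ]
  a1 <- tab[tab$variant == "ensemble" & tab$alpha == 1, ]
  gbm_row <- tab[tab$variant == "gbm", ]
  cnn_row <- tab[tab$variant == "boosted_cnn", ]
  for (nm in ldaboost:::METRIC_NAMES) {
    expect_equal(a0[[nm]], gbm_row[[nm]])    # alpha = 0 is the tree head
    expect_equal(a1[[nm]], cnn_row[[nm]])    # alpha = 1 is the boosted CNN
  }
  expect_setequal(unique(tab$variant),
                  c("ensemble", "boosted_cnn", "adaboost", "gbm"))
})

test_that("candidate ranking excludes known associations and orders scores", {
  sim <- small_sim()
  fit <- cached("fit_small",
                ldaboost(sim$am, e = 6, cnn = list(Q = 2, epochs = 2),
                         gbm = list(n_estimators = 30), seed = 6))
  dis <- colnames(sim$am)[which.max(colSums(sim$am))]
  top <- rank_candidates(fit, dis, k = 15)
  expect_lte(nrow(top), 15)
  known <- rownames(sim$am)[unclass(sim$am)[, dis] == 1L]
  expect_length(intersect(top$lncRNA_id, known), 0)
  expect_true(all(diff(top$fused_score) <= 0))
  # k = n returns every unassociated lncRNA
  all_free <- rank_candidates(fit, dis, k = nrow(sim$am))
  expect_equal(nrow(all_free), nrow(sim$am) - length(known))
  expect_error(rank_candidates(fit, "no-such-disease"), "unknown disease")
})

test_that("the fitted model predicts coherently over pairs", {
  sim <- small_sim()
  fit <- cached("fit_small",
                ldaboost(sim$am, e = 6, cnn = list(Q = 2, epochs = 2),
                         gbm = list(n_estimators = 30), seed = 6))
  all_scores <- predict(fit)
  expect_equal(nrow(all_scores), nrow(sim$am) * ncol(sim$am))
  expect_equal(all_scores$fused_score,
               fuse_scores(all_scores$c_score, all_scores$f_score, fit$alpha))
  some <- predict(fit, pairs = cbind(c("L1", "L2"), c("D3", "D4")))
  expect_equal(nrow(some), 2)
  expect_error(predict(fit, pairs = cbind("L1", "nope")), "unknown")
  s <- summary(fit)
  expect_gt(s$training_metrics$auc, 0.7)
})
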