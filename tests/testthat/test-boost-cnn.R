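test_that("sample weights initialize uniform and sum to one", {
  expect_equal(init_sample_weights(4), rep(0.25, 4))
  for (p in c(1, 7, 100)) expect_equal(sum(init_sample_weights(p)), 1)
  expect_error(init_sample_weights(0), "positive integer")
  expect_error(init_sample_weights(-3), "positive integer")
})

test_that("weight vector stays a distribution after every round", {
  ds <- small_dataset()
  m <- cached("bcnn_small", train_boosted_cnn(ds, Q = 6, epochs = 2, seed = 4))
  for (D in m$D_history) {
    expect_equal(sum(D), 1, tolerance = 1e-9)
    expect_true(all(D >= 0))
  }
  expect_length(m$D_history, m$Q + 1L)
})

test_that("misclassified weights rise when a round beats chance", {
  m <- cached("bcnn_small", train_boosted_cnn(small_dataset(), Q = 6,
                                              epochs = 2, seed = 4))
  checked <- 0L
  for (q in seq_len(m$Q)) {
    miss <- m$miss_history[[q]]
    if (m$round_log$weighted_error[q] < 0.5 && length(miss)) {
      ratio <- m$D_history[[q + 1L]][miss] / m$D_history[[q]][miss]
      expect_gte(min(ratio), 1 - 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("the symmetric log-odds map matches hand-computed values", {
  # uniform probabilities contribute exactly zero
  expect_equal(ldaboost:::samme_contrib(matrix(0.5, 1, 2)),
               matrix(0, 1, 2))
  # two stub estimators: o1 = (.8, .2), o2 = (.6, .4)
  c1 <- ldaboost:::samme_contrib(matrix(c(0.8, 0.2), 1))
  c2 <- ldaboost:::samme_contrib(matrix(c(0.6, 0.4), 1))
  agg1 <- c1[1] + c2[1]
  expect_equal(agg1, 0.5 * log(0.8 / 0.2) + 0.5 * log(0.6 / 0.4))
  expect_equal(agg1, 0.8959, tolerance = 1e-4)
  expect_gt(agg1, 0)                      # -> association class
  # probability floor keeps zero probabilities finite
  expect_true(all(is.finite(ldaboost:::samme_contrib(matrix(c(0, 1), 1)))))
})

test_that("a Q=1 ensemble is the standalone CNN (aggregation identity)", {
  ds <- small_dataset()
  X <- ds$X[1:120, ]; y <- ds$y[1:120]
  sub <- list(X = X, y = y)
  m <- train_boosted_cnn(sub, Q = 1, epochs = 2, seed = 21)
  solo <- ldaboost:::train_cnn(X, y, weights = init_sample_weights(nrow(X)),
                               cfg = m$cfg, epochs = 2,
                               seed = ldaboost:::derive_seed(21, 1L))
  expect_identical(solo$params, m$estimators[[1]]$params)
  sc <- boosted_cnn_scores(m, X)
  probs <- ldaboost:::cnn_probs(m$estimators[[1]], X)
  expect_identical(sc$label, as.integer(probs[, 1] > probs[, 2]))
  # at Q = 1 the log-odds aggregation inverts exactly: score = p1
  expect_equal(sc$score, probs[, 1], tolerance = 1e-9)
})

test_that("boosting improves fit and is reproducible bit for bit", {
  ds <- small_dataset()
  m <- cached("bcnn_small", train_boosted_cnn(ds, Q = 6, epochs = 2, seed = 4))
  m2 <- train_boosted_cnn(ds, Q = 6, epochs = 2, seed = 4)
  s1 <- boosted_cnn_scores(m, ds$X)
  expect_identical(s1$score, boosted_cnn_scores(m2, ds$X)$score)
  # better than chance on its training data
  expect_gt(compute_metrics(ds$y, s1$score)$auc, 0.8)
  # scores live in [0, 1]
  expect_true(all(s1$score >= 0 & s1$score <= 1))
})

test_that("degenerate inputs are rejected", {
  ds <- small_dataset()
  one_class <- list(X = ds$X[ds$y == 1, ], y = ds$y[ds$y == 1])
  expect_error(train_boosted_cnn(one_class, Q = 2, epochs = 1),
               "single class")
  bad <- list(X = ds$X, y = ds$y); bad$X[1, 1] <- NaN
  expect_error(train_boosted_cnn(bad, Q = 2, epochs = 1), "non-finite")
  expect_error(train_boosted_cnn(ds, Q = 0, epochs = 1), ">= 1")
})

test_that("boosted ensembles survive a save/load round trip bitwise", {
  ds <- small_dataset()
  m <- cached("bcnn_small", train_boosted_cnn(ds, Q = 6, epochs = 2, seed = 4))
  dir <- file.path(tempdir(), "bcnn_saved")
  save_boosted_cnn(m, dir)
  m2 <- load_boosted_cnn(dir)
  expect_equal(boosted_cnn_scores(m2, ds$X[1:50, ])$score,
               boosted_cnn_scores(m, ds$X[1:50, ])$score)
  unlink(dir, recursive = TRUE)
})
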