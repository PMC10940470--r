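# Shared fixtures, built in code. `.fixture_cache` memoizes the expensive
# ones so test files can reuse them without retraining.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 2x2 matrix with three associations: [[1,1],[0,1]]
tiny_am <- function() {
  assoc_matrix(matrix(c(1L, 0L, 1L, 1L), 2, 2),
               lnc_ids = c("L1", "L2"), dis_ids = c("D1", "D2"))
}

write_edge_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Moderate planted-structure problem used by several training tests.
small_sim <- function() cached("small_sim", {
  simulate_association_matrix(synthetic_spec(40, 50, r = 3, density = 0.12,
                                             noise = 0, seed = 3))
})

small_dataset <- function() cached("small_dataset", {
  sim <- small_sim()
  f <- svd_factorize(sim$am, 6)
  assemble_dataset(sim$am, features = f, seed = 3)
})

# Linearly separable 8-sample toy problem in R^4.
toy_separable <- function() {
  X <- rbind(
    c(2.0, 1.5, 0.1, 0.2), c(1.8, 2.2, -0.1, 0.1),
    c(2.5, 1.9, 0.0, -0.2), c(2.1, 2.4, 0.2, 0.0),
    c(-2.0, -1.5, 0.1, 0.0), c(-1.8, -2.1, -0.2, 0.1),
    c(-2.4, -1.7, 0.0, 0.2), c(-2.2, -2.3, 0.1, -0.1)
  )
  list(X = X, y = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
}

# Brute-force metric oracles, independent of compute_metrics() internals:
# explicit confusion-matrix counting, pairwise positive-negative comparison
# for AUC (ties one half), step integration down the ranked list for AUPR.
oracle_metrics <- function(y, s, thr = 0.5) {
  pred <- ifelse(s >= thr, 1L, 0L)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y)) {
    if (pred[i] == 1L && y[i] == 1L) tp <- tp + 1L
    if (pred[i] == 1L && y[i] == 0L) fp <- fp + 1L
    if (pred[i] == 0L && y[i] == 0L) tn <- tn + 1L
    if (pred[i] == 0L && y[i] == 1L) fn <- fn + 1L
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  wins <- 0; npairs <- 0
  for (i in which(y == 1L)) for (j in which(y == 0L)) {
    npairs <- npairs + 1
    wins <- wins + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  ord <- order(-s, seq_along(s))
  tp_c <- 0; ap <- 0; prev_rec <- 0; npos <- sum(y == 1L)
  for (k in seq_along(ord)) {
    if (y[ord[k]] == 1L) tp_c <- tp_c + 1
    rec_k <- tp_c / npos
    ap <- ap + (rec_k - prev_rec) * (tp_c / k)
    prev_rec <- rec_k
  }
  list(precision = prec, recall = rec, accuracy = (tp + tn) / length(y),
       f1 = f1, auc = wins / npairs, aupr = ap)
}

# Test-profile hyperparameters (reduced from the study defaults Q = 100,
# epochs = 10 so the suite stays fast): Q = 10, epochs = 3, e = 8.
test_profile <- function(seed = 1L) {
  list(e = 8L, cnn = list(Q = 10L, epochs = 3L), seed = seed)
}
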