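#' Assemble a labeled pair dataset from an association matrix
#'
#' Turns matrix cells into labeled samples for the pair classifier. Two
#' sampling modes are supported: `"all_pairs"` enumerates every cell
#' (\eqn{p = n \times m} samples), while `"balanced"` keeps all positive
#' cells and draws `floor(neg_ratio * #positives)` zero cells uniformly
#' without replacement as presumed negatives. The sample order is shuffled
#' deterministically by `seed`.
#'
#' @param am an [assoc_matrix()].
#' @param features optional feature provider: a function `(row, col) ->
#'   numeric vector` or an [svd_factorization()] (in which case concatenated
#'   pair features are used). `NULL` returns pairs and labels only.
#' @param mode `"balanced"` (default) or `"all_pairs"`.
#' @param neg_ratio positive real, negatives drawn per positive (balanced
#'   mode only).
#' @param seed integer controlling negative sampling and shuffling.
#' @param scaling feature scaling forwarded to [pair_features()] when
#'   `features` is a factorization.
#' @return A list of class `labeled_dataset` with elements `X` (p x d
#'   feature matrix, `NULL` if no provider), `y` (0/1 integer labels),
#'   `pairs` (p x 2 integer matrix of row/col indices), and the identifier
#'   vectors.
#' @export
assemble_dataset <- function(am, features = NULL, mode = c("balanced", "all_pairs"),
                             neg_ratio = 1, seed = 1L,
                             scaling = c("sqrt_sigma", "raw")) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  stopifnot(inherits(am, "assoc_matrix"))
  n <- nrow(am); m <- ncol(am)
  pos <- which(unclass(am) == 1L)
  neg <- which(unclass(am) == 0L)
  if (mode == "all_pairs") {
    cells <- seq_len(n * m)
  } else {
    if (!is.numeric(neg_ratio) || neg_ratio <= 0)
      stop("neg_ratio must be a positive real")
    n_neg <- floor(neg_ratio * length(pos))
    if (n_neg > length(neg))
      stop(sprintf("insufficient zero cells: %d negatives requested, %d available",
                   n_neg, length(neg)))
    set.seed(derive_seed(seed, 101L))
    cells <- c(pos, sample(neg, n_neg))
  }
  set.seed(derive_seed(seed, 102L))
  cells <- sample(cells)
  rows <- (cells - 1L) %% n + 1L
  cols <- (cells - 1L) %/% n + 1L
  y <- as.integer(unclass(am)[cells])
  X <- NULL
  if (!is.null(features)) {
    if (inherits(features, "svd_factorization")) {
      X <- pair_feature_matrix(features, cbind(rows, cols), scaling = scaling)
    } else {
      X <- t(mapply(features, rows, cols))
    }
  }
  structure(
    list(X = X, y = y, pairs = cbind(row = rows, col = cols),
         lnc_ids = rownames(am), dis_ids = colnames(am)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled lncRNA-disease pair dataset: %d samples (%d positive), %s\n",
              length(x$y), sum(x$y),
              if (is.null(x$X)) "no features attached"
              else sprintf("d = %d features", ncol(x$X))))
  invisible(x)
}
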