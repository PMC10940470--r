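#' Truncated SVD factorization of the association matrix
#'
#' Computes the singular value decomposition \eqn{Y = U \Sigma V^T} and keeps
#' the `e` largest singular triplets, giving the best rank-`e` approximation
#' of the binary association matrix in Frobenius norm (Eckart-Young). Rows of
#' the truncated \eqn{U_e} embed lncRNAs, rows of \eqn{V_e} embed diseases.
#'
#' The factorization is made bit-reproducible by a sign convention: the
#' largest-magnitude entry of each column of \eqn{U_e} is made positive
#' (ties resolved to the first index), with the matching \eqn{V_e} column
#' flipped accordingly.
#'
#' If `Y` has rank below `e` (possible after masking held-out cells),
#' trailing triplets with zero singular value are retained as zero feature
#' components so the feature width stays fixed.
#'
#' @param am an [assoc_matrix()], or any numeric matrix (a masked copy is
#'   accepted so cross-validation can zero held-out cells first).
#' @param e truncation rank, `1 <= e <= min(n, m)`.
#' @return An object of class `svd_factorization`: list with `U` (n x e),
#'   `sigma` (length e, non-increasing, >= 0), `V` (m x e), `e`, and the
#'   identifier vectors when available.
#' @export
svd_factorize <- function(am, e) {
  Y <- unclass(as.matrix(am))
  storage.mode(Y) <- "double"
  n <- nrow(Y); m <- ncol(Y)
  if (!is.numeric(e) || length(e) != 1L || e < 1 || e != round(e))
    stop("e must be a positive integer")
  e <- as.integer(e)
  if (e > min(n, m))
    stop(sprintf("e = %d out of range: must be <= min(n, m) = %d", e, min(n, m)))
  if (all(Y == 0)) stop("all-zero matrix has no informative factors")
  s <- svd(Y, nu = e, nv = e)
  sigma <- s$d[seq_len(e)]
  sigma[sigma < .Machine$double.eps * max(n, m) * s$d[1L]] <- 0
  U <- s$u; V <- s$v
  # sign convention: largest-|.| entry of each U column positive, ties -> first
  for (k in seq_len(e)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  structure(
    list(U = U, sigma = sigma, V = V, e = e,
         lnc_ids = rownames(am), dis_ids = colnames(am)),
    class = "svd_factorization"
  )
}

#' @export
print.svd_factorization <- function(x, ...) {
  cat(sprintf("Truncated SVD factorization: rank e = %d, sigma = [%s]\n",
              x$e, paste(signif(x$sigma, 4), collapse = ", ")))
  invisible(x)
}

#' Per-entity feature vector from a truncated factorization
#'
#' Returns the length-`e` embedding of one lncRNA (a row of \eqn{U_e}) or
#' one disease (a row of \eqn{V_e}). With `scaling = "sqrt_sigma"` the row is
#' multiplied elementwise by \eqn{\sqrt{\sigma}}, splitting the singular
#' values symmetrically between the two sides so that the inner product of a
#' lncRNA and a disease feature approximates the matrix entry \eqn{y_{ij}}.
#' `"raw"` returns the orthonormal singular-vector rows unscaled.
#'
#' @param f an [svd_factorize()] result.
#' @param axis `"lncrna"` or `"disease"`.
#' @param index 1-based entity index along the chosen axis.
#' @param scaling `"sqrt_sigma"` (default) or `"raw"`.
#' @return Numeric vector of length `e`.
#' @export
entity_features <- function(f, axis = c("lncrna", "disease"), index,
                            scaling = c("sqrt_sigma", "raw")) {
  axis <- match.arg(axis)
  scaling <- match.arg(scaling)
  M <- if (axis == "lncrna") f$U else f$V
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > nrow(M))
    stop(sprintf("index %s out of bounds for axis %s (1..%d)",
                 format(index), axis, nrow(M)))
  v <- M[as.integer(index), ]
  if (scaling == "sqrt_sigma") v <- v * sqrt(f$sigma)
  v
}

#' Concatenated pair feature vector
#'
#' Concatenates the lncRNA embedding and the disease embedding into the
#' length-`d = 2e` feature vector used by the pair classifiers: the first
#' `e` entries are the lncRNA features, the last `e` the disease features.
#'
#' @inheritParams entity_features
#' @param row lncRNA index.
#' @param col disease index.
#' @return Numeric vector of length `2e`.
#' @export
pair_features <- function(f, row, col, scaling = c("sqrt_sigma", "raw")) {
  c(entity_features(f, "lncrna", row, scaling),
    entity_features(f, "disease", col, scaling))
}

# Vectorized pair feature construction for many (row, col) pairs at once.
pair_feature_matrix <- function(f, pairs, scaling = c("sqrt_sigma", "raw")) {
  scaling <- match.arg(scaling)
  U <- f$U; V <- f$V
  if (scaling == "sqrt_sigma") {
    sc <- sqrt(f$sigma)
    U <- sweep(U, 2L, sc, `*`)
    V <- sweep(V, 2L, sc, `*`)
  }
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > nrow(U)) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > nrow(V)))
    stop("pair index out of bounds")
  cbind(U[pairs[, 1L], , drop = FALSE], V[pairs[, 2L], , drop = FALSE])
}

#' Rank-e reconstruction of the association matrix
#'
#' @param f an [svd_factorize()] result.
#' @return The n x m matrix \eqn{U_e \Sigma_e V_e^T}.
#' @export
svd_reconstruct <- function(f) {
  f$U %*% (f$sigma * t(f$V))
}

# Zero held-out positive cells before factorization (leakage control for
# cross-validation). `cells` is a 2-column (row, col) index matrix.
mask_cells <- function(am, cells) {
  Y <- unclass(as.matrix(am))
  if (length(cells)) Y[cells] <- 0L
  Y
}
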