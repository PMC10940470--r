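# Deterministic child-seed derivation: every stochastic step draws its own
# seed from the user's master seed so components can be re-run in isolation.
# Values stay inside the 32-bit signed range R requires for set.seed().
derive_seed <- function(seed, k) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) x <- (x * 48271 + as.double(k) * 16807 + i) %% 2147483647
  as.integer(x)
}

#' Construct a binary lncRNA-disease association matrix
#'
#' Wraps a binary incidence matrix \eqn{Y \in \{0,1\}^{n \times m}} (rows:
#' lncRNAs, columns: diseases) together with stable identifier orderings.
#' Entry \eqn{y_{ij} = 1} records a known association between lncRNA
#' \eqn{l_i} and disease \eqn{d_j}.
#'
#' @param Y numeric or integer matrix of 0/1 entries with at least one 1.
#' @param lnc_ids character vector of unique lncRNA identifiers (row names).
#' @param dis_ids character vector of unique disease identifiers (col names).
#' @return An object of class `assoc_matrix`: the 0/1 integer matrix with
#'   `dimnames` set, carrying `n`, `m` and the identifier vectors.
#' @export
assoc_matrix <- function(Y, lnc_ids = rownames(Y), dis_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(lnc_ids)) lnc_ids <- paste0("L", seq_len(nrow(Y)))
  if (is.null(dis_ids)) dis_ids <- paste0("D", seq_len(ncol(Y)))
  lnc_ids <- as.character(lnc_ids)
  dis_ids <- as.character(dis_ids)
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop("association matrix must have at least one row and one column")
  if (length(lnc_ids) != nrow(Y) || length(dis_ids) != ncol(Y))
    stop("identifier lengths must match matrix dimensions")
  if (anyDuplicated(lnc_ids)) stop("duplicate lncRNA identifiers")
  if (anyDuplicated(dis_ids)) stop("duplicate disease identifiers")
  if (!all(Y %in% c(0, 1))) stop("entries of Y must all be 0 or 1")
  if (sum(Y) < 1) stop("no associations: matrix contains no 1 entries")
  storage.mode(Y) <- "integer"
  dimnames(Y) <- list(lnc_ids, dis_ids)
  structure(Y, class = c("assoc_matrix", "matrix", "array"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "Binary lncRNA-disease association matrix: %d lncRNAs x %d diseases, %d associations (density %.4f)\n",
    nrow(x), ncol(x), sum(x), mean(x)
  ))
  invisible(x)
}

#' Read an association edge list
#'
#' Parses a delimited edge list with one `(lncRNA_id, disease_id)` pair per
#' line and builds the binary association matrix. Rows and columns are
#' ordered by first appearance in the file; duplicate edges collapse to a
#' single 1 with a warning. Lines starting with `#` are comments; a header
#' line reading `lncRNA_id<delim>disease_id` (any case) is skipped.
#'
#' @param path path to a UTF-8 text file.
#' @param delimiter single-character field separator (default tab).
#' @return An [assoc_matrix()].
#' @export
load_association_edges <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # optional ordering directives written by write_association_edges(); they
  # pin identifier order (and keep zero-degree entities) across a round trip
  ord <- function(tag) {
    hit <- grep(paste0("^#! ", tag, ": "), raw, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(sub(paste0("^#! ", tag, ": "), "", hit[[1L]]),
             delimiter, fixed = TRUE)[[1L]]
  }
  lnc_order <- ord("lncRNA_order")
  dis_order <- ord("disease_order")
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) > 0L) {
    first <- tolower(strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]])
    if (length(first) >= 2L && first[[1L]] %in% c("lncrna_id", "lncrna") &&
        first[[2L]] %in% c("disease_id", "disease")) {
      lines <- lines[-1L]
      lineno <- lineno[-1L]
    }
  }
  if (length(lines) == 0L) stop("no associations: empty edge list in ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed line ", lineno[which(nf < 2L)[1L]],
         ": expected at least 2 delimited fields")
  lnc <- trimws(vapply(parts, `[[`, "", 1L))
  dis <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(lnc == "" | dis == ""))
    stop("malformed line ", lineno[which(lnc == "" | dis == "")[1L]],
         ": empty identifier")
  if (anyDuplicated(paste0(lnc, "\r", dis)))
    warning("duplicate edges collapsed to single associations")
  lnc_ids <- if (is.null(lnc_order)) unique(lnc) else lnc_order
  dis_ids <- if (is.null(dis_order)) unique(dis) else dis_order
  if (!all(lnc %in% lnc_ids) || !all(dis %in% dis_ids))
    stop("edge identifiers not covered by ordering directives")
  Y <- matrix(0L, length(lnc_ids), length(dis_ids),
              dimnames = list(lnc_ids, dis_ids))
  Y[cbind(match(lnc, lnc_ids), match(dis, dis_ids))] <- 1L
  assoc_matrix(Y, lnc_ids, dis_ids)
}

#' Write an association matrix back to an edge list
#'
#' Inverse of [load_association_edges()]: emits one `(lncRNA_id, disease_id)`
#' line per association, ordered so that re-loading reproduces the identical
#' matrix and identifier orderings (row-major by first appearance).
#'
#' @param am an [assoc_matrix()].
#' @param path output file path.
#' @param delimiter field separator.
#' @param header logical; write a `lncRNA_id/disease_id` header line.
#' @export
write_association_edges <- function(am, path, delimiter = "\t", header = TRUE) {
  idx <- which(t(unclass(am)) == 1L)  # row-major so row order is preserved
  m <- ncol(am)
  i <- (idx - 1L) %/% m + 1L
  j <- (idx - 1L) %% m + 1L
  lines <- paste(rownames(am)[i], colnames(am)[j], sep = delimiter)
  lines <- c(
    paste0("#! lncRNA_order: ", paste(rownames(am), collapse = delimiter)),
    paste0("#! disease_order: ", paste(colnames(am), collapse = delimiter)),
    lines
  )
  if (header)
    lines <- c(paste("lncRNA_id", "disease_id", sep = delimiter), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
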