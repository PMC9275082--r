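#' Read a miRNA-target pair list
#'
#' Two-column delimited text (miRNA id, target id); lines starting with `#`
#' are comments. Any whitespace or comma delimiter is accepted.
#'
#' @param path Path to the pair list.
#' @return data.frame with character columns `mirna`, `target`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          sep = "", colClasses = "character",
                          col.names = c("mirna", "target"))
  if (ncol(df) != 2) stop("pair list must have exactly two columns")
  df
}

#' Write a miRNA-target pair list
#' @param pairs data.frame with columns `mirna`, `target`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("mirna", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the binary association matrix A from a pair list
#'
#' @param pairs data.frame (or 2-column matrix) of known positive pairs:
#'   first column miRNA id, second column target id.
#' @param mirna_ids,target_ids Orderings of the node sets. Defaults to the
#'   order of first appearance in `pairs`.
#' @return M x N binary matrix with miRNA ids as rownames and target ids as
#'   colnames; entry 1 iff the pair is a known positive.
#' @export
association_matrix <- function(pairs, mirna_ids = NULL, target_ids = NULL) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("pairs must have two columns (miRNA, target)")
  mi <- as.character(pairs[[1]])
  tg <- as.character(pairs[[2]])
  if (is.null(mirna_ids)) mirna_ids <- unique(mi)
  if (is.null(target_ids)) target_ids <- unique(tg)
  if (anyDuplicated(mirna_ids) || anyDuplicated(target_ids))
    stop("node ids must be unique")
  i <- match(mi, mirna_ids)
  j <- match(tg, target_ids)
  if (anyNA(i) || anyNA(j))
    stop("pair list references ids absent from the supplied id vectors")
  A <- matrix(0, length(mirna_ids), length(target_ids),
              dimnames = list(mirna_ids, target_ids))
  A[cbind(i, j)] <- 1
  A
}

#' Positive pairs of an association matrix as an index matrix
#'
#' @param A Association matrix.
#' @return Integer matrix with columns `mirna`, `target` (1-based indices),
#'   in column-major order of `A`.
#' @export
positive_pairs <- function(A) {
  idx <- which(A == 1)
  cbind(mirna = ((idx - 1L) %% nrow(A)) + 1L,
        target = ((idx - 1L) %/% nrow(A)) + 1L)
}

#' Mask held-out test edges out of an association matrix
#'
#' Returns a copy of `A` with the given test positives set to 0, so the
#' training graph never sees a held-out link. Every pair in `test_pairs` must
#' be a positive of `A`.
#'
#' @param A Association matrix.
#' @param test_pairs Integer matrix/data.frame with two columns (miRNA index,
#'   target index), or character ids resolved against the dimnames of `A`.
#' @return Masked copy of `A`.
#' @export
mask_test_edges <- function(A, test_pairs) {
  idx <- resolve_pairs(A, test_pairs)
  if (nrow(idx) == 0) return(A)
  if (any(A[idx] != 1))
    stop("test pairs must all be positives of A")
  A2 <- A
  A2[idx] <- 0
  A2
}

# resolve a 2-column pair spec (integer indices or character ids) to an
# integer index matrix against A's dimnames
resolve_pairs <- function(A, pairs) {
  pairs <- as.matrix(as.data.frame(pairs))
  if (nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  if (is.character(pairs)) {
    i <- match(pairs[, 1], rownames(A))
    j <- match(pairs[, 2], colnames(A))
    if (anyNA(i) || anyNA(j)) stop("unknown ids in pair list")
    cbind(i, j)
  } else {
    storage.mode(pairs) <- "integer"
    if (any(pairs[, 1] < 1 | pairs[, 1] > nrow(A)) ||
        any(pairs[, 2] < 1 | pairs[, 2] > ncol(A)))
      stop("pair indices out of range")
    pairs[, 1:2, drop = FALSE]
  }
}
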