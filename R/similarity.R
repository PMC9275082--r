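#' Pairwise similarity between sequence feature vectors
#'
#' Computes a square symmetric similarity matrix between the rows of a feature
#' matrix under one of four measures:
#' \describe{
#'   \item{jaccard}{intersection over union of binary vectors,
#'     `S_ij = |x_i & x_j| / |x_i | x_j|`; requires binary input. The 0/0 case
#'     (two all-zero rows) is defined as 0, so an all-zero row has
#'     self-similarity 0 while any non-zero row has self-similarity 1.}
#'   \item{cosine}{`<x_i, x_j> / (|x_i| |x_j|)`; zero-norm rows get similarity
#'     0 with a warning.}
#'   \item{pearson}{cosine of the row-centred vectors (the ordinary Pearson
#'     correlation between rows); constant rows get 0 with a warning.}
#'   \item{gaussian}{`exp(-|x_i - x_j|^2 / (2 sigma^2))` with bandwidth
#'     `sigma^2` equal to the mean squared pairwise distance over the set
#'     (degenerate all-equal input gives similarity 1 everywhere).}
#' }
#'
#' @param f Numeric feature matrix, rows = entities (e.g. from
#'   [kmer_features()]); must be binary for `"jaccard"`.
#' @param measure Similarity measure.
#' @return Symmetric similarity matrix with the row ids of `f` as dimnames and
#'   attribute `measure`.
#' @export
similarity_matrix <- function(f,
                              measure = c("jaccard", "cosine", "pearson",
                                          "gaussian")) {
  measure <- match.arg(measure)
  f <- as.matrix(f)
  S <- switch(measure,
    jaccard  = jaccard_similarity(f),
    cosine   = cosine_sim(f),
    pearson  = cosine_sim(f - rowMeans(f), what = "pearson"),
    gaussian = gaussian_sim(f)
  )
  dimnames(S) <- list(rownames(f), rownames(f))
  attr(S, "measure") <- measure
  attr(S, "normalized") <- FALSE
  S
}

#' Jaccard index between all row pairs of a binary matrix
#'
#' @param f Binary matrix (entries 0/1).
#' @return Symmetric matrix of Jaccard indices in `[0, 1]`.
#' @export
jaccard_similarity <- function(f) {
  f <- as.matrix(f)
  if (!all(f %in% c(0, 1)))
    stop("jaccard similarity requires a binary feature matrix")
  inter <- tcrossprod(f)              # |x_i & x_j|
  s <- rowSums(f)
  uni <- outer(s, s, "+") - inter     # |x_i | x_j|
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(rownames(f), rownames(f))
  S
}

cosine_sim <- function(f, what = "cosine") {
  nrm <- sqrt(rowSums(f^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " zero-norm row(s) in ", what,
            " similarity; similarity set to 0")
  nrm[zero] <- 1
  fn <- f / nrm
  S <- tcrossprod(fn)
  S[zero, ] <- 0
  S[, zero] <- 0
  # guard tiny numerical overshoot
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

gaussian_sim <- function(f) {
  s2 <- rowSums(f^2)
  d2 <- outer(s2, s2, "+") - 2 * tcrossprod(f)
  d2[d2 < 0] <- 0
  n <- nrow(f)
  off <- d2[upper.tri(d2)]
  sigma2 <- if (length(off)) mean(off) else 0
  if (sigma2 <= 0) {
    matrix(1, n, n)
  } else {
    exp(-d2 / (2 * sigma2))
  }
}

#' Symmetric degree normalization of a similarity matrix
#'
#' Returns `D^{-1/2} S D^{-1/2}` where `D = diag(rowSums(S))`. Rows with zero
#' degree are left as zero (guarded division). Negative entries (possible for
#' the Pearson measure) are clamped to zero first with a warning, since graph
#' degrees must be non-negative.
#'
#' @param S Symmetric similarity matrix.
#' @return Normalized symmetric matrix; attribute `normalized` set to `TRUE`.
#' @export
normalize_similarity <- function(S) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  if (any(S < 0)) {
    warning("negative similarity entries clamped to 0 before normalization")
    S[S < 0] <- 0
  }
  out <- degree_normalize(S)
  dimnames(out) <- dimnames(S)
  attr(out, "measure") <- attr(S, "measure")
  attr(out, "normalized") <- TRUE
  out
}

#' Symmetric degree normalization D^{-1/2} G D^{-1/2}
#'
#' The normalization used both for the similarity networks and for the
#' propagation graph of the encoder. Zero-degree rows/columns are left zero.
#'
#' @param G Symmetric non-negative matrix.
#' @return `D^{-1/2} G D^{-1/2}`.
#' @export
degree_normalize <- function(G) {
  G <- as.matrix(G)
  if (any(G < 0)) stop("degree normalization requires non-negative entries")
  d <- rowSums(G)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  G * outer(inv, inv)
}

#' Write a similarity matrix as labeled TSV plus sparse MTX with an id index
#'
#' Writes three files: `<prefix>.tsv` (dense, row/column labels),
#' `<prefix>.mtx` (MatrixMarket sparse triplets) and `<prefix>.ids`
#' (one id per line, the row order of the matrix).
#'
#' @param S Similarity matrix with dimnames.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_similarity <- function(S, prefix) {
  tsv <- paste0(prefix, ".tsv")
  mtx <- paste0(prefix, ".mtx")
  ids <- paste0(prefix, ".ids")
  utils::write.table(S, tsv, sep = "\t", quote = FALSE, col.names = NA)
  Matrix::writeMM(methods::as(Matrix::Matrix(unclass(S), sparse = TRUE),
                              "generalMatrix"), mtx)
  writeLines(rownames(S), ids)
  invisible(c(tsv = tsv, mtx = mtx, ids = ids))
}
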