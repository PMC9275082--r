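#' Heterogeneous adjacency matrix over miRNAs and targets
#'
#' Assembles the (M+N) x (M+N) block matrix
#' `[[S_m, A], [t(A), S_n]]` combining the normalized within-type similarity
#' networks with the across-type association matrix.
#'
#' @param A M x N association matrix.
#' @param Sm M x M normalized miRNA-miRNA similarity.
#' @param Sn N x N normalized target-target similarity.
#' @return Symmetric (M+N) x (M+N) matrix.
#' @export
hetero_adjacency <- function(A, Sm, Sn) {
  check_blocks(A, Sm, Sn)
  H <- rbind(cbind(unclass(Sm), A), cbind(t(A), unclass(Sn)))
  ids <- c(rownames(A), colnames(A))
  if (length(ids) == nrow(H)) dimnames(H) <- list(ids, ids)
  H
}

#' Propagation graph and initial embedding for the GCN encoder
#'
#' Builds the input graph `G = [[mu * S_m, A], [t(A), mu * S_n]]`, where the
#' penalty factor `mu` controls how much the similarity networks contribute to
#' propagation, and the initial embedding `H0 = [[0, A], [t(A), 0]]` (the pure
#' bipartite adjacency). With `mu = 0` the encoder propagates over the
#' bipartite association graph alone.
#'
#' The similarity diagonal (scaled by `mu`) acts as the self-loop term of `G`;
#' no extra identity is added.
#'
#' @param A M x N association matrix (train-masked when evaluating).
#' @param Sm,Sn Normalized similarity matrices (see [normalize_similarity()]).
#' @param mu Non-negative similarity penalty factor (default 0.06).
#' @return Object of class `hetero_graph`: list with elements `G`, `H0`,
#'   `mu`, `M`, `N`, `mirna_ids`, `target_ids`.
#' @export
propagation_graph <- function(A, Sm, Sn, mu = 0.06) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0)
  check_blocks(A, Sm, Sn)
  M <- nrow(A); N <- ncol(A)
  G <- rbind(cbind(mu * unclass(Sm), A), cbind(t(A), mu * unclass(Sn)))
  Z_m <- matrix(0, M, M)
  Z_n <- matrix(0, N, N)
  H0 <- rbind(cbind(Z_m, A), cbind(t(A), Z_n))
  dimnames(G) <- dimnames(H0) <-
    list(c(rownames(A), colnames(A)), c(rownames(A), colnames(A)))
  structure(list(G = G, H0 = H0, mu = mu, M = M, N = N,
                 mirna_ids = rownames(A), target_ids = colnames(A)),
            class = "hetero_graph")
}

check_blocks <- function(A, Sm, Sn) {
  if (nrow(Sm) != ncol(Sm) || nrow(Sn) != ncol(Sn))
    stop("similarity matrices must be square")
  if (nrow(Sm) != nrow(A) || nrow(Sn) != ncol(A))
    stop(sprintf(paste0("block shape mismatch: A is %dx%d but similarity ",
                        "blocks are %dx%d (miRNA) and %dx%d (target)"),
                 nrow(A), ncol(A), nrow(Sm), ncol(Sm), nrow(Sn), ncol(Sn)))
  invisible(TRUE)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("Heterogeneous miRNA-target graph\n")
  cat(sprintf("  %d miRNAs + %d targets (%d nodes); mu = %g\n",
              x$M, x$N, x$M + x$N, x$mu))
  cat(sprintf("  known associations: %d\n", sum(x$H0[seq_len(x$M),
              x$M + seq_len(x$N)])))
  invisible(x)
}

#' Serialize a heterogeneous graph to sparse MTX plus a JSON sidecar
#'
#' Writes `<prefix>.G.mtx`, `<prefix>.H0.mtx` and `<prefix>.json` (holding
#' M, N, mu and the id lists).
#'
#' @param graph `hetero_graph` object.
#' @param prefix Output path prefix.
#' @export
write_hetero_graph <- function(graph, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$G, sparse = TRUE),
                              "generalMatrix"), paste0(prefix, ".G.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$H0, sparse = TRUE),
                              "generalMatrix"), paste0(prefix, ".H0.mtx"))
  side <- list(M = graph$M, N = graph$N, mu = graph$mu,
               mirna_ids = graph$mirna_ids, target_ids = graph$target_ids)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a heterogeneous graph written by [write_hetero_graph()]
#' @param prefix Path prefix used when writing.
#' @return `hetero_graph` object.
#' @export
read_hetero_graph <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  G <- as.matrix(Matrix::readMM(paste0(prefix, ".G.mtx")))
  H0 <- as.matrix(Matrix::readMM(paste0(prefix, ".H0.mtx")))
  storage.mode(G) <- storage.mode(H0) <- "double"
  ids <- c(side$mirna_ids, side$target_ids)
  dimnames(G) <- dimnames(H0) <- list(ids, ids)
  structure(list(G = G, H0 = H0, mu = side$mu, M = side$M, N = side$N,
                 mirna_ids = side$mirna_ids, target_ids = side$target_ids),
            class = "hetero_graph")
}
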