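# Shared fixtures and independent oracles used across test files.

random_binary_matrix <- function(n, p, density = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * p, 1, density), n, p,
         dimnames = list(paste0("r", seq_len(n)), NULL))
}

# brute-force Jaccard via explicit set operations, one pair at a time
jaccard_set_oracle <- function(f) {
  n <- nrow(f)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- which(f[i, ] == 1)
      xj <- which(f[j, ] == 1)
      u <- length(union(xi, xj))
      S[i, j] <- if (u == 0) 0 else length(intersect(xi, xj)) / u
    }
  }
  S
}

# dense closed-form D^{-1/2} S D^{-1/2} with explicit diagonal matrices
degree_normalize_oracle <- function(S) {
  d <- rowSums(S)
  Dih <- diag(ifelse(d > 0, 1 / sqrt(d), 0))
  Dih %*% S %*% Dih
}

# random symmetric non-negative matrix
random_sym_matrix <- function(n, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  (S + t(S)) / 2
}

# small graph + params ready for forward/backward, no dropout
tiny_model_setup <- function(M = 5, N = 7, k = 3, L = 3, seed = 42,
                             variant = "attention") {
  set.seed(seed)
  A <- matrix(rbinom(M * N, 1, 0.3), M, N)
  if (sum(A) == 0) A[1, 1] <- 1
  if (sum(A) == length(A)) A[1, 1] <- 0
  Sm <- normalize_similarity(random_sym_matrix(M, seed + 1))
  Sn <- normalize_similarity(random_sym_matrix(N, seed + 2))
  g <- propagation_graph(A, Sm, Sn, mu = 0.06)
  cfg <- gcn_config(embed_dim = k, n_layers = L, node_dropout = 0,
                    edge_dropout = 0, variant = variant)
  cfg$M <- M
  cfg$node_masks <- NULL
  set.seed(seed + 3)
  params <- gcnlink:::init_params(M + N, cfg)
  list(A = A, Sm = Sm, Sn = Sn, graph = g,
       Gn = degree_normalize(g$G), cfg = cfg, params = params,
       pos = which(A == 1), neg = which(A == 0))
}

# memoised expensive computations shared between acceptance tests
.accept_cache <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.accept_cache$data)) {
    d <- synth_generate(synth_config())
    d$Sm <- normalize_similarity(similarity_matrix(kmer_features(d$mirna_seqs)))
    d$Sn <- normalize_similarity(similarity_matrix(kmer_features(d$target_seqs)))
    .accept_cache$data <- d
  }
  .accept_cache$data
}

acceptance_cv <- function() {
  if (is.null(.accept_cache$cv)) {
    d <- acceptance_dataset()
    .accept_cache$cv <- cross_validate(d$A, d$Sm, d$Sn, task = "balanced",
                                       strategy = "SCT", n_folds = 5,
                                       seeds = 1:3)
  }
  .accept_cache$cv
}
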