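# GCN encoder with layer attention and bilinear decoder, with hand-written
# analytic gradients (verified against finite differences in the test suite).

#' Model configuration for the GCN link predictor
#'
#' @param embed_dim Embedding dimensionality k (default 64).
#' @param n_layers Number of graph-convolution layers L (default 3).
#' @param node_dropout Coarse-grained node dropout probability alpha in
#'   `[0, 1)` (default 0.6), applied during training only.
#' @param edge_dropout Fine-grained edge dropout probability beta in `[0, 1)`
#'   (default 0.6), applied to the non-zero entries of the normalized
#'   propagation graph during training only.
#' @param variant Which embedding combination feeds the decoder:
#'   `"attention"` (learned softmax weights over layers, the default),
#'   `"average"` (fixed equal weights), `"concat"` (stack the L embeddings;
#'   the decoder weight becomes Lk x Lk), or `"layer1"`/`"layer2"`/`"layer3"`
#'   (a single layer's embedding).
#' @param node_dropout_on Where node dropout acts: `"embedding"` masks whole
#'   embedding rows (default), `"graph"` masks rows of the propagation matrix.
#' @return List of class `gcn_config`.
#' @export
gcn_config <- function(embed_dim = 64L, n_layers = 3L,
                       node_dropout = 0.6, edge_dropout = 0.6,
                       variant = c("attention", "average", "concat",
                                   "layer1", "layer2", "layer3"),
                       node_dropout_on = c("embedding", "graph")) {
  variant <- match.arg(variant)
  node_dropout_on <- match.arg(node_dropout_on)
  stopifnot(embed_dim >= 1, n_layers >= 1,
            node_dropout >= 0, node_dropout < 1,
            edge_dropout >= 0, edge_dropout < 1)
  if (grepl("^layer", variant)) {
    l <- as.integer(sub("layer", "", variant))
    if (l > n_layers)
      stop("variant ", variant, " needs at least ", l, " layers")
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 node_dropout = node_dropout, edge_dropout = edge_dropout,
                 variant = variant, node_dropout_on = node_dropout_on),
            class = "gcn_config")
}

#' One graph-convolution layer
#'
#' Computes `activation(G_norm %*% H %*% W)`, the layer-wise propagation rule
#' of the encoder. `G_norm` must already be symmetric degree-normalized.
#'
#' @param H Input embedding (n x d).
#' @param G_norm Normalized propagation matrix (n x n).
#' @param W Layer weight (d x k).
#' @param activation Activation function (default [selu()]).
#' @return n x k embedding matrix.
#' @export
gcn_layer <- function(H, G_norm, W, activation = selu) {
  if (ncol(G_norm) != nrow(H) || ncol(H) != nrow(W))
    stop("shape mismatch in gcn_layer")
  activation(G_norm %*% (H %*% W))
}

#' Softmax layer attention over a stack of embeddings
#'
#' Combines L per-layer embeddings into `sum_l a_l H^(l)` with
#' `a = softmax(logits)`.
#'
#' @param layers List of L equally-shaped embedding matrices.
#' @param logits Numeric vector of L attention logits.
#' @return List with `weights` (the softmax weights, summing to 1) and
#'   `combined` (the weighted embedding sum).
#' @export
layer_attention <- function(layers, logits) {
  stopifnot(length(layers) == length(logits))
  a <- softmax(logits)
  combined <- a[1] * layers[[1]]
  if (length(layers) > 1)
    for (l in 2:length(layers)) combined <- combined + a[l] * layers[[l]]
  list(weights = a, combined = combined)
}

#' Bilinear decoder scores
#'
#' `sigmoid(H_I %*% W %*% t(H_G))`: every miRNA-target pair scored in (0, 1).
#'
#' @param H_I M x k miRNA embeddings.
#' @param H_G N x k target embeddings.
#' @param W k x k decoder weight.
#' @return M x N score matrix.
#' @export
bilinear_scores <- function(H_I, H_G, W) {
  if (ncol(H_I) != nrow(W) || ncol(H_G) != ncol(W))
    stop("embedding/decoder dimension mismatch")
  sigmoid(H_I %*% W %*% t(H_G))
}

# ---- parameter initialisation ------------------------------------------------

init_params <- function(n_nodes, cfg) {
  k <- cfg$embed_dim
  L <- cfg$n_layers
  params <- list(W1 = xavier_init(n_nodes, k))
  if (L > 1)
    for (l in 2:L) params[[paste0("W", l)]] <- xavier_init(k, k)
  dec_dim <- if (cfg$variant == "concat") L * k else k
  params$Wdec <- xavier_init(dec_dim, dec_dim)
  if (cfg$variant == "attention") params$att <- rep(0, L)
  params
}

trainable_names <- function(params) names(params)

# ---- forward / backward ------------------------------------------------------

# masks: NULL (no dropout) or list(node = list of length-n scale vectors per
# layer (embedding mode) or NULL, graph-mode dropout is baked into Gd).
gcn_forward <- function(Gd, H0, params, cfg) {
  L <- cfg$n_layers
  Z <- vector("list", L)
  X <- vector("list", L)
  Xprev <- H0
  for (l in seq_len(L)) {
    Z[[l]] <- Gd %*% (Xprev %*% params[[paste0("W", l)]])
    A <- selu(Z[[l]])
    X[[l]] <- if (!is.null(cfg$node_masks)) A * cfg$node_masks[[l]] else A
    Xprev <- X[[l]]
  }
  att_w <- attention_weights(params, cfg)
  if (cfg$variant == "concat") {
    Hc <- do.call(cbind, X)
  } else {
    Hc <- att_w[1] * X[[1]]
    if (L > 1) for (l in 2:L) Hc <- Hc + att_w[l] * X[[l]]
  }
  M <- cfg$M
  HI <- Hc[seq_len(M), , drop = FALSE]
  HG <- Hc[(M + 1):nrow(Hc), , drop = FALSE]
  S <- HI %*% params$Wdec %*% t(HG)
  list(Z = Z, X = X, a = att_w, Hc = Hc, HI = HI, HG = HG,
       S = S, P = sigmoid(S))
}

attention_weights <- function(params, cfg) {
  L <- cfg$n_layers
  switch(cfg$variant,
    attention = softmax(params$att),
    average   = rep(1 / L, L),
    concat    = NULL,
    {
      l <- as.integer(sub("layer", "", cfg$variant))
      w <- rep(0, L); w[l] <- 1; w
    })
}

# delta = dLoss/dS (M x N). Returns gradients for every entry of `params`.
gcn_backward <- function(fwd, Gd, H0, params, cfg, delta) {
  L <- cfg$n_layers
  k <- cfg$embed_dim
  M <- cfg$M
  HI <- fwd$HI; HG <- fwd$HG
  grads <- list()
  grads$Wdec <- crossprod(HI, delta %*% HG)
  dHI <- delta %*% HG %*% t(params$Wdec)
  dHG <- crossprod(delta, HI %*% params$Wdec)
  dHc <- rbind(dHI, dHG)

  dX <- vector("list", L)
  if (cfg$variant == "concat") {
    for (l in seq_len(L)) dX[[l]] <- dHc[, ((l - 1) * k + 1):(l * k),
                                         drop = FALSE]
  } else {
    a <- fwd$a
    for (l in seq_len(L)) dX[[l]] <- a[l] * dHc
    if (cfg$variant == "attention") {
      da <- vapply(seq_len(L), function(l) sum(dHc * fwd$X[[l]]), 0)
      grads$att <- a * (da - sum(a * da))
    }
  }

  tGd <- t(Gd)
  for (l in rev(seq_len(L))) {
    dA <- if (!is.null(cfg$node_masks)) dX[[l]] * cfg$node_masks[[l]]
          else dX[[l]]
    dZ <- dA * selu_grad(fwd$Z[[l]])
    Tl <- tGd %*% dZ
    Xprev <- if (l == 1) H0 else fwd$X[[l - 1]]
    grads[[paste0("W", l)]] <- crossprod(Xprev, Tl)
    if (l > 1)
      dX[[l - 1]] <- dX[[l - 1]] + Tl %*% t(params[[paste0("W", l)]])
  }
  grads[names(params)]
}

# ---- loss --------------------------------------------------------------------

#' Imbalance-weighted cross-entropy over known and unobserved pairs
#'
#' `loss = -(1/(M*N)) * (lambda * sum_{pos} log A'_ij +
#'   sum_{neg} log(1 - A'_ij))` with the balance factor
#' `lambda = |neg| / |pos|` emphasising the scarce known associations.
#' Log arguments are clamped at 1e-12 for numerical stability.
#'
#' @param scores M x N score matrix (entries in (0, 1)).
#' @param positives 2-column index matrix of known-positive pairs.
#' @param negatives 2-column index matrix of unobserved (negative) pairs.
#' @param lambda Optional override of the balance factor; defaults to
#'   `nrow(negatives) / nrow(positives)`.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(scores, positives, negatives,
                                   lambda = NULL) {
  if (NROW(positives) == 0)
    stop("positive set is empty; the balance factor lambda is undefined")
  if (NROW(negatives) == 0 && is.null(lambda))
    stop("negative set is empty; the balance factor lambda is undefined")
  pos <- as.matrix(positives)[, 1:2, drop = FALSE]
  neg <- as.matrix(negatives)[, 1:2, drop = FALSE]
  if (is.null(lambda)) lambda <- nrow(neg) / nrow(pos)
  wce_at(scores, scores[pos], if (nrow(neg)) scores[neg] else numeric(0),
         lambda)
}

# internal fast path on pre-extracted score vectors
wce_at <- function(scores, p_pos, p_neg, lambda) {
  MN <- length(scores)
  -(lambda * sum(log(pmax(p_pos, 1e-12))) +
      sum(log(pmax(1 - p_neg, 1e-12)))) / MN
}

# dLoss/dS at linear indices (pos_idx, neg_idx) of the M x N score matrix
wce_delta <- function(P, pos_idx, neg_idx, lambda) {
  delta <- matrix(0, nrow(P), ncol(P))
  delta[pos_idx] <- -lambda * (1 - P[pos_idx])
  delta[neg_idx] <- P[neg_idx]
  delta / length(P)
}
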