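#' Fit the GCN link-prediction model to sequences and known associations
#'
#' High-level interface: builds binary k-mer features for both sequence sets,
#' the within-type similarity networks, the heterogeneous propagation graph,
#' and trains the graph-convolutional encoder with layer attention and a
#' bilinear decoder by minimising the imbalance-weighted cross-entropy
#' (Adam, triangular cyclic learning rate, Xavier initialisation, edge/node
#' dropout).
#'
#' @param pairs data.frame of known positive pairs (miRNA id, target id).
#' @param mirna_seqs,target_seqs Named character vectors of sequences (RNA or
#'   DNA alphabet), or paths handled by [read_fasta()] upstream.
#' @param k k-mer length for the sequence features (default 3).
#' @param measure Similarity measure (default `"jaccard"`).
#' @param mu Similarity penalty factor in the propagation graph (default 0.06).
#' @param config Model configuration from [gcn_config()].
#' @param epochs Training epochs (default 500).
#' @param lr_low,lr_high Cyclic learning-rate bounds (defaults 0.01 and 0.1).
#' @param exclude Optional pairs (ids or indices) excluded from the training
#'   loss entirely — typically held-out test positives, which are also masked
#'   out of the graph via [mask_test_edges()] before calling this function.
#' @param seed Integer seed controlling initialisation and dropout.
#' @param verbose Print progress every 100 epochs.
#' @return Object of class `gcn_link`; see [gcn_link_fit()] for components.
#' @seealso [gcn_link_fit()] for the matrix-level interface,
#'   [cross_validate()] for evaluation.
#' @export
gcn_link <- function(pairs, mirna_seqs, target_seqs, k = 3L,
                     measure = "jaccard", mu = 0.06,
                     config = gcn_config(), epochs = 500L,
                     lr_low = 0.01, lr_high = 0.1,
                     exclude = NULL, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  mirna_seqs <- normalize_sequences(mirna_seqs)
  target_seqs <- normalize_sequences(target_seqs)
  A <- association_matrix(pairs, names(mirna_seqs), names(target_seqs))
  Fm <- kmer_features(mirna_seqs, k = k)
  Fn <- kmer_features(target_seqs, k = k)
  Sm <- normalize_similarity(similarity_matrix(Fm, measure))
  Sn <- normalize_similarity(similarity_matrix(Fn, measure))
  if (!is.null(exclude)) {
    exclude <- resolve_pairs(A, exclude)
    A <- mask_test_edges(A, exclude)
  }
  fit <- gcn_link_fit(A, Sm, Sn, mu = mu, config = config, epochs = epochs,
                      lr_low = lr_low, lr_high = lr_high, exclude = exclude,
                      seed = seed, verbose = verbose)
  fit$call <- cl
  fit$kmer_k <- k
  fit$measure <- measure
  fit
}

#' Fit the GCN link-prediction model from matrices
#'
#' Matrix-level fitting routine: takes the (train-masked) association matrix
#' and the two normalized similarity matrices, assembles the propagation
#' graph, and runs full-batch gradient training.
#'
#' Training pairs: the positives are the 1-entries of `A`; the negatives are
#' all remaining pairs except those listed in `exclude` (held-out test
#' positives must never be counted as training negatives).
#'
#' @inheritParams gcn_link
#' @param A M x N binary association matrix (already masked for evaluation).
#' @param Sm,Sn Normalized similarity matrices ([normalize_similarity()]).
#' @return Object of class `gcn_link` with components `params` (weights),
#'   `attention` (softmax layer weights, when applicable), `fitted_scores`
#'   (M x N score matrix from the final state, no dropout), `loss_trace`
#'   (per-epoch loss), `lambda` (imbalance weight), `config`, `mu`, `A`,
#'   `mirna_ids`, `target_ids`, `seed`.
#' @export
gcn_link_fit <- function(A, Sm, Sn, mu = 0.06, config = gcn_config(),
                         epochs = 500L, lr_low = 0.01, lr_high = 0.1,
                         exclude = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "gcn_config"), epochs >= 1)
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("association matrix must be binary")
  if (is.null(rownames(A)))
    rownames(A) <- paste0("miRNA_", seq_len(nrow(A)))
  if (is.null(colnames(A)))
    colnames(A) <- paste0("target_", seq_len(ncol(A)))
  graph <- propagation_graph(A, Sm, Sn, mu = mu)
  M <- graph$M; N <- graph$N; n <- M + N
  Gn <- degree_normalize(graph$G)
  H0 <- graph$H0

  pos_idx <- which(A == 1)
  excl_idx <- integer(0)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    ex <- resolve_pairs(A, exclude)
    excl_idx <- (ex[, 2] - 1L) * M + ex[, 1]
    if (any(A[excl_idx] == 1))
      stop("excluded pairs must not be positives of the masked matrix")
  }
  if (length(pos_idx) == 0) stop("no positive pairs to train on")
  neg_idx <- setdiff(which(A == 0), excl_idx)
  if (length(neg_idx) == 0)
    stop("no unobserved pairs: the negative set is empty and the ",
         "imbalance weight lambda is undefined")
  lambda <- length(neg_idx) / length(pos_idx)

  cfg <- config
  cfg$M <- M
  cfg$node_masks <- NULL
  L <- cfg$n_layers
  alpha <- cfg$node_dropout
  beta <- cfg$edge_dropout
  # undirected edges: drop the two symmetric entries together
  nz_ut <- which(Gn != 0 & upper.tri(Gn, diag = TRUE))
  nz_i <- ((nz_ut - 1L) %% n) + 1L
  nz_j <- ((nz_ut - 1L) %/% n) + 1L
  nz_lo <- (nz_i - 1L) * n + nz_j

  set.seed(as.integer(seed) %% .Machine$integer.max)
  params <- init_params(n, cfg)
  opt <- adam_init(params)
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    lr <- cyclic_lr(ep - 1L, lr_low, lr_high)
    Gd <- Gn
    if (beta > 0) {
      keep <- stats::rbinom(length(nz_ut), 1L, 1 - beta) / (1 - beta)
      Gd[nz_ut] <- Gn[nz_ut] * keep
      Gd[nz_lo] <- Gn[nz_lo] * keep
    }
    tcfg <- cfg
    if (alpha > 0) {
      if (cfg$node_dropout_on == "embedding") {
        tcfg$node_masks <- lapply(seq_len(L), function(l)
          stats::rbinom(n, 1L, 1 - alpha) / (1 - alpha))
      } else {
        rowkeep <- stats::rbinom(n, 1L, 1 - alpha) / (1 - alpha)
        Gd <- Gd * rowkeep
      }
    }
    fwd <- gcn_forward(Gd, H0, params, tcfg)
    loss <- wce_at(fwd$P, fwd$P[pos_idx], fwd$P[neg_idx], lambda)
    if (!is.finite(loss))
      stop(sprintf("training diverged at epoch %d (loss = %g); %s", ep, loss,
                   "try a lower learning rate or dropout"))
    loss_trace[ep] <- loss
    delta <- wce_delta(fwd$P, pos_idx, neg_idx, lambda)
    grads <- gcn_backward(fwd, Gd, H0, params, tcfg, delta)
    step <- adam_step(params, grads, opt, lr)
    params <- step$params
    opt <- step$state
    if (verbose && ep %% 100 == 0)
      message(sprintf("epoch %4d  loss %.5f  lr %.3f", ep, loss, lr))
  }

  eval_fwd <- gcn_forward(Gn, H0, params, cfg)
  scores <- eval_fwd$P
  dimnames(scores) <- dimnames(A)
  structure(list(
    params = params,
    attention = eval_fwd$a,
    fitted_scores = scores,
    loss_trace = loss_trace,
    lambda = lambda,
    config = config,
    mu = mu, epochs = as.integer(epochs),
    lr_low = lr_low, lr_high = lr_high,
    A = A, excluded = excl_idx,
    mirna_ids = rownames(A), target_ids = colnames(A),
    seed = as.integer(seed),
    call = match.call()
  ), class = "gcn_link")
}

# ---- S3 methods --------------------------------------------------------------

#' @export
print.gcn_link <- function(x, ...) {
  cat("Graph-convolutional miRNA-target link predictor\n")
  cat(sprintf("  %d miRNAs x %d targets, %d known associations\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  cat(sprintf("  encoder: %d layers, k = %d, variant = %s, mu = %g\n",
              x$config$n_layers, x$config$embed_dim, x$config$variant, x$mu))
  cat(sprintf("  trained %d epochs; final loss %.5f\n",
              x$epochs, utils::tail(x$loss_trace, 1)))
  if (!is.null(x$attention))
    cat("  layer attention:",
        paste(sprintf("%.3f", x$attention), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gcn_link <- function(object, ...) {
  tr_pairs <- length(object$A) - length(object$excluded)
  out <- list(
    M = nrow(object$A), N = ncol(object$A), n_pos = sum(object$A),
    n_train_pairs = tr_pairs, lambda = object$lambda,
    config = object$config, mu = object$mu, epochs = object$epochs,
    initial_loss = object$loss_trace[1],
    final_loss = utils::tail(object$loss_trace, 1),
    attention = object$attention,
    score_range = range(object$fitted_scores)
  )
  class(out) <- "summary.gcn_link"
  out
}

#' @export
print.summary.gcn_link <- function(x, ...) {
  cat("GCN link predictor fit\n")
  cat(sprintf("  nodes: %d miRNAs + %d targets; positives: %d of %d training pairs\n",
              x$M, x$N, x$n_pos, x$n_train_pairs))
  cat(sprintf("  imbalance weight lambda = %.3f\n", x$lambda))
  cat(sprintf("  loss: %.5f -> %.5f over %d epochs\n",
              x$initial_loss, x$final_loss, x$epochs))
  if (!is.null(x$attention))
    cat("  layer attention weights:",
        paste(sprintf("%.3f", x$attention), collapse = " "), "\n")
  cat(sprintf("  score range: [%.4f, %.4f]\n",
              x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' Extract model weights
#'
#' @param object A `gcn_link` fit.
#' @param component `"all"` (list of every weight), `"attention"` (softmax
#'   layer weights) or `"decoder"`.
#' @param ... Unused.
#' @export
coef.gcn_link <- function(object, component = c("all", "attention",
                                                "decoder"), ...) {
  component <- match.arg(component)
  switch(component,
         all = object$params,
         attention = object$attention,
         decoder = object$params$Wdec)
}

#' Predict association scores
#'
#' @param object A `gcn_link` fit.
#' @param newdata Optional pairs to score: a data.frame/matrix of (miRNA,
#'   target) ids or indices. With `newdata = NULL`, `type = "matrix"` returns
#'   the full M x N score matrix and `type = "ranked"` a data.frame of all
#'   unobserved pairs ranked by decreasing score (training positives
#'   excluded).
#' @param type Output form (ignored when `newdata` is given).
#' @param ... Unused.
#' @export
predict.gcn_link <- function(object, newdata = NULL,
                             type = c("matrix", "ranked"), ...) {
  type <- match.arg(type)
  P <- object$fitted_scores
  if (!is.null(newdata)) {
    idx <- resolve_pairs(object$A, newdata)
    return(P[idx])
  }
  if (type == "matrix") return(P)
  unobs <- which(object$A == 0)
  i <- ((unobs - 1L) %% nrow(P)) + 1L
  j <- ((unobs - 1L) %/% nrow(P)) + 1L
  out <- data.frame(mirna = object$mirna_ids[i],
                    target = object$target_ids[j],
                    score = P[unobs], stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' @export
fitted.gcn_link <- function(object, ...) object$fitted_scores

#' Raw residuals A - A' on training-visible pairs
#'
#' Held-out (excluded) pairs are returned as `NA` since they carry no
#' training signal.
#'
#' @param object A `gcn_link` fit.
#' @param ... Unused.
#' @export
residuals.gcn_link <- function(object, ...) {
  r <- object$A - object$fitted_scores
  if (length(object$excluded)) r[object$excluded] <- NA_real_
  r
}

#' Diagnostic plot: loss trace and layer-attention weights
#'
#' @param x A `gcn_link` fit.
#' @param ... Passed to `plot()` for the loss trace.
#' @export
plot.gcn_link <- function(x, ...) {
  has_att <- !is.null(x$attention)
  if (has_att) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "weighted cross-entropy",
                 main = "Training loss", ...)
  if (has_att)
    graphics::barplot(x$attention,
                      names.arg = paste0("layer ", seq_along(x$attention)),
                      ylab = "attention weight", main = "Layer attention")
  invisible(x)
}

#' Simulate association matrices from the fitted score matrix
#'
#' Draws Bernoulli matrices with success probabilities equal to the fitted
#' scores.
#'
#' @param object A `gcn_link` fit.
#' @param nsim Number of simulated matrices.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` binary M x N matrices.
#' @export
simulate.gcn_link <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- object$fitted_scores
  lapply(seq_len(nsim), function(s) {
    B <- matrix(stats::rbinom(length(P), 1L, P), nrow(P), ncol(P))
    dimnames(B) <- dimnames(P)
    B
  })
}
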