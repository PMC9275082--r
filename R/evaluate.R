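#' Partition positive pairs into cross-validation folds
#'
#' Shuffled partition of `n` items (or of the rows of a pair matrix) into
#' `n_folds` parts whose sizes differ by at most one.
#'
#' @param positives Number of positive pairs, or a 2-column pair matrix.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `n_folds` integer index vectors (indices into the positive
#'   set), pairwise disjoint, union = all indices.
#' @export
make_folds <- function(positives, n_folds = 5L, seed = 1L) {
  n <- if (length(positives) == 1 && is.numeric(positives)) as.integer(positives)
       else nrow(as.matrix(positives))
  stopifnot(n_folds >= 2)
  if (n < n_folds) stop("fewer positives than folds")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  perm <- sample.int(n)
  fold_of <- rep(seq_len(n_folds), length.out = n)
  lapply(seq_len(n_folds), function(f) sort(perm[fold_of == f]))
}

#' Sample negative (unobserved) miRNA-target pairs
#'
#' Three strategies:
#' \describe{
#'   \item{random}{uniform draw without replacement over all non-positive,
#'     non-excluded pairs.}
#'   \item{SCM}{sampling by miRNA: each miRNA with `p_i` positives contributes
#'     `p_i` negatives incident to it per round; rounds repeat until the quota
#'     is met (for the 1:20 unbalanced ratio), skipping exhausted miRNAs.}
#'   \item{SCT}{the symmetric strategy over targets.}
#' }
#' SCM/SCT guarantee that every miRNA/target holding at least one positive and
#' one free negative is represented in the sample. The collected pool is
#' truncated to exactly `n_needed` by a seeded subsample.
#'
#' @param A Full binary association matrix (sampled negatives are never known
#'   positives).
#' @param n_needed Number of negatives to draw.
#' @param strategy `"random"`, `"SCM"` or `"SCT"`.
#' @param seed Integer seed.
#' @param exclude Optional pairs (indices or ids) additionally excluded from
#'   the candidate pool.
#' @return Integer matrix with columns `mirna`, `target`.
#' @export
sample_negatives <- function(A, n_needed,
                             strategy = c("random", "SCM", "SCT"),
                             seed = 1L, exclude = NULL) {
  strategy <- match.arg(strategy)
  A <- as.matrix(A)
  M <- nrow(A); N <- ncol(A)
  excl_idx <- integer(0)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    ex <- resolve_pairs(A, exclude)
    excl_idx <- (ex[, 2] - 1L) * M + ex[, 1]
  }
  candidates <- setdiff(which(A == 0), excl_idx)
  if (n_needed > length(candidates))
    stop("not enough available negative pairs (",
         length(candidates), " < ", n_needed, ")")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  if (strategy == "random") {
    picked <- sample(candidates, n_needed)
  } else {
    by_row <- strategy == "SCM"
    p <- if (by_row) rowSums(A) else colSums(A)
    # per-entity candidate pools (linear indices)
    ent_of <- if (by_row) ((candidates - 1L) %% M) + 1L
              else ((candidates - 1L) %/% M) + 1L
    pools <- split(candidates, factor(ent_of, levels = seq_along(p)))
    pools <- lapply(pools, function(v) v[sample.int(length(v))])  # shuffle
    taken <- integer(length(p))                   # consumed per entity
    picked <- integer(0)
    starved <- which(p > 0 & lengths(pools) == 0)
    if (length(starved))
      warning("entities with positives but no available negatives skipped: ",
              length(starved))
    repeat {
      added <- 0L
      for (e in seq_along(p)) {
        if (p[e] == 0) next
        avail <- lengths(pools)[e] - taken[e]
        take <- min(p[e], avail)
        if (take > 0) {
          picked <- c(picked, pools[[e]][taken[e] + seq_len(take)])
          taken[e] <- taken[e] + take
          added <- added + take
        }
      }
      if (length(picked) >= n_needed || added == 0L) break
    }
    if (length(picked) < n_needed)
      stop("per-entity sampling exhausted after ", length(picked),
           " of ", n_needed, " negatives")
    if (length(picked) > n_needed)
      picked <- sample(picked, n_needed)
  }
  cbind(mirna = ((picked - 1L) %% M) + 1L,
        target = ((picked - 1L) %/% M) + 1L)
}

#' Ranking and threshold metrics for scored pairs
#'
#' AUC is computed by the midrank (Mann-Whitney) statistic, AUPR by
#' step-wise integration of the precision-recall curve (precision held at its
#' value to the right of each recall increment; ties processed as blocks).
#' The remaining five metrics come from the confusion matrix at `threshold`.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 vector, same length; both classes must be present.
#' @param threshold Classification threshold on the sigmoid scores
#'   (default 0.5).
#' @return Named list of class `metrics_report`: `aupr`, `auc`, `f1`,
#'   `accuracy`, `recall`, `specificity`, `precision`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1); Nn <- sum(labels == 0)
  if (P == 0 || Nn == 0)
    stop("both classes must be present to compute ranking metrics")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * Nn)

  # PR curve over tie blocks, scores decreasing
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  block_end <- which(diff(s) != 0)
  block_end <- c(block_end, length(s))
  tp <- cumsum(y)[block_end]
  n_seen <- block_end
  prec <- tp / n_seen
  rec <- tp / P
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- TP / (TP + FN)
  specificity <- TN / (TN + FP)
  accuracy <- (TP + TN) / length(labels)
  f1 <- if (precision + recall > 0) 2 * precision * recall /
          (precision + recall) else 0
  structure(list(aupr = aupr, auc = auc, f1 = f1, accuracy = accuracy,
                 recall = recall, specificity = specificity,
                 precision = precision),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%-12s %.4f", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Five-fold cross-validation of the link predictor
#'
#' For each seed and fold: the test positives are masked out of the training
#' graph and excluded from the training loss, the model is fitted, and the
#' test positives plus sampled negatives (1 per positive for the balanced
#' task, 20 per positive for the unbalanced task) are scored and summarised
#' by the seven-metric report.
#'
#' @param A Full binary association matrix.
#' @param Sm,Sn Normalized similarity matrices.
#' @param task `"balanced"` (1:1 test negatives) or `"unbalanced"` (1:20).
#' @param strategy Negative-sampling strategy for the test sets
#'   (`"SCT"` default, `"SCM"` or `"random"`).
#' @param n_folds Number of folds (default 5).
#' @param seeds Integer vector; the whole CV is repeated per seed.
#' @param mu,config,epochs,lr_low,lr_high Passed to [gcn_link_fit()].
#' @param verbose Report per-fold progress.
#' @return Object of class `gcn_link_cv`: list with `per_fold` (data.frame of
#'   seed, fold, the seven metrics and the attention weights when the variant
#'   learns them) and `summary` (mean and sd per metric).
#' @export
cross_validate <- function(A, Sm, Sn, task = c("balanced", "unbalanced"),
                           strategy = "SCT", n_folds = 5L, seeds = 1L,
                           mu = 0.06, config = gcn_config(), epochs = 500L,
                           lr_low = 0.01, lr_high = 0.1, verbose = FALSE) {
  task <- match.arg(task)
  ratio <- if (task == "balanced") 1L else 20L
  A <- as.matrix(A)
  pos <- positive_pairs(A)
  rows <- list()
  for (seed in seeds) {
    folds <- make_folds(nrow(pos), n_folds = n_folds, seed = seed)
    for (f in seq_len(n_folds)) {
      test_pos <- pos[folds[[f]], , drop = FALSE]
      A_train <- mask_test_edges(A, test_pos)
      fit <- gcn_link_fit(A_train, Sm, Sn, mu = mu, config = config,
                          epochs = epochs, lr_low = lr_low,
                          lr_high = lr_high, exclude = test_pos,
                          seed = seed * 1000L + f)
      test_neg <- sample_negatives(A, ratio * nrow(test_pos), strategy,
                                   seed = seed * 1000L + 500L + f)
      sc <- c(fit$fitted_scores[test_pos], fit$fitted_scores[test_neg])
      lab <- c(rep(1L, nrow(test_pos)), rep(0L, nrow(test_neg)))
      m <- compute_metrics(sc, lab)
      row <- data.frame(seed = seed, fold = f,
                        n_test_pos = nrow(test_pos),
                        n_test_neg = nrow(test_neg),
                        as.data.frame(unclass(m)))
      if (!is.null(fit$attention) && config$variant == "attention")
        for (l in seq_along(fit$attention))
          row[[paste0("att", l)]] <- fit$attention[l]
      rows[[length(rows) + 1L]] <- row
      if (verbose)
        message(sprintf("seed %d fold %d: AUC %.3f AUPR %.3f",
                        seed, f, m$auc, m$aupr))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("seed", "fold"))
  summ <- data.frame(metric = metric_cols,
                     mean = vapply(per_fold[metric_cols], mean, 0),
                     sd = vapply(per_fold[metric_cols], stats::sd, 0),
                     row.names = NULL)
  structure(list(per_fold = per_fold, summary = summ, task = task,
                 strategy = strategy, n_folds = n_folds, seeds = seeds),
            class = "gcn_link_cv")
}

#' @export
print.gcn_link_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %s task, %s sampling, %d seed(s)\n",
              x$n_folds, x$task, x$strategy, length(x$seeds)))
  main <- x$summary[x$summary$metric %in%
                      c("aupr", "auc", "f1", "accuracy", "recall",
                        "specificity", "precision"), ]
  for (i in seq_len(nrow(main)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", main$metric[i], main$mean[i],
                main$sd[i]))
  invisible(x)
}

#' Write a cross-validation report and prediction dump
#'
#' `<prefix>_report.tsv` holds long-format (seed, fold, metric, value) rows
#' plus `mean`/`sd` summary rows; the return value of [cross_validate()] is
#' the in-memory equivalent.
#'
#' @param cv A `gcn_link_cv` object.
#' @param prefix Output path prefix.
#' @export
write_cv_report <- function(cv, prefix) {
  pf <- cv$per_fold
  metric_cols <- setdiff(names(pf), c("seed", "fold"))
  long <- do.call(rbind, lapply(metric_cols, function(mc)
    data.frame(seed = pf$seed, fold = pf$fold, metric = mc,
               value = pf[[mc]])))
  summ <- data.frame(seed = NA, fold = NA,
                     metric = c(paste0(cv$summary$metric, "_mean"),
                                paste0(cv$summary$metric, "_sd")),
                     value = c(cv$summary$mean, cv$summary$sd))
  out <- paste0(prefix, "_report.tsv")
  utils::write.table(rbind(long, summ), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
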