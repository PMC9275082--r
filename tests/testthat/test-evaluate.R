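test_that("fold partition is balanced, disjoint and exhaustive", {
  folds <- make_folds(3745, 5, seed = 1)
  expect_equal(lengths(folds), rep(749, 5))
  expect_equal(3745 - lengths(folds), rep(2996, 5))  # per-fold training size

  folds2 <- make_folds(10, 5, seed = 2)
  expect_equal(lengths(folds2), rep(2, 5))

  for (n in c(23, 57)) {
    fl <- make_folds(n, 5, seed = n)
    expect_equal(sort(unlist(fl)), 1:n)
    expect_lte(diff(range(lengths(fl))), 1)
  }
  expect_error(make_folds(3, 5), "fewer positives")
})

test_that("negative samplers never return a known positive and hit the quota", {
  set.seed(4)
  A <- matrix(rbinom(15 * 40, 1, 0.2), 15, 40)
  for (strategy in c("random", "SCM", "SCT")) {
    neg <- sample_negatives(A, 100, strategy, seed = 11)
    expect_equal(nrow(neg), 100)
    expect_true(all(A[neg] == 0))
    expect_equal(anyDuplicated(paste(neg[, 1], neg[, 2])), 0)
    # determinism / seed sensitivity
    neg2 <- sample_negatives(A, 100, strategy, seed = 11)
    expect_identical(neg, neg2)
    neg3 <- sample_negatives(A, 100, strategy, seed = 12)
    expect_false(identical(neg, neg3))
  }
  expect_error(sample_negatives(A, 1e5, "random"), "not enough")
})

test_that("exclusions are honoured by every sampler", {
  set.seed(5)
  A <- matrix(rbinom(8 * 12, 1, 0.3), 8, 12)
  zeros <- which(A == 0)
  excl <- cbind(((zeros[1:10] - 1) %% 8) + 1, ((zeros[1:10] - 1) %/% 8) + 1)
  for (strategy in c("random", "SCM", "SCT")) {
    # exclusions can starve an entity entirely; that path warns by design
    neg <- suppressWarnings(
      sample_negatives(A, 30, strategy, seed = 3, exclude = excl))
    got <- paste(neg[, 1], neg[, 2])
    expect_false(any(got %in% paste(excl[, 1], excl[, 2])))
  }
})

test_that("per-entity coverage holds on an enumerable 5x8 toy", {
  A <- matrix(0, 5, 8)
  A[1, 1:3] <- 1; A[2, 4] <- 1; A[3, 5:6] <- 1; A[4, 7] <- 1
  # miRNA 5 has no positives; target 8 has no positives
  for (seed in 1:10) {
    neg <- sample_negatives(A, 7, "SCM", seed = seed)
    covered <- unique(neg[, 1])
    for (i in 1:4) expect_true(i %in% covered)  # every miRNA with a positive
    expect_equal(nrow(neg), 7)
  }
  for (seed in 1:10) {
    neg <- sample_negatives(A, 7, "SCT", seed = seed)
    covered <- unique(neg[, 2])
    for (j in c(1:7)) expect_true(j %in% covered)
  }
})

test_that("SCM/SCT loop rounds satisfy large unbalanced quotas", {
  set.seed(6)
  A <- matrix(rbinom(10 * 30, 1, 0.15), 10, 30)
  quota <- 20 * 10  # far beyond one per-entity round
  neg <- sample_negatives(A, quota, "SCT", seed = 2)
  expect_equal(nrow(neg), quota)
  expect_true(all(A[neg] == 0))
})

test_that("metrics are exact on separable and degenerate score vectors", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  for (v in unlist(m)) expect_equal(v, 1)

  m2 <- compute_metrics(rep(0.3, 10), c(rep(1, 4), rep(0, 6)))
  expect_equal(m2$auc, 0.5)   # midrank tie convention
  expect_error(compute_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC equals the brute-force concordance count", {
  set.seed(8)
  scores <- round(runif(12), 2)
  labels <- rbinom(12, 1, 0.5)
  labels[1] <- 1; labels[2] <- 0
  m <- compute_metrics(scores, labels)
  conc <- 0
  for (i in which(labels == 1)) for (j in which(labels == 0))
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(m$auc, conc / (sum(labels == 1) * sum(labels == 0)),
               tolerance = 1e-12)
})

test_that("AUC and AUPR agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.4)
  m <- compute_metrics(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
    direction = "<", quiet = TRUE)))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-10)

  # step-integrated AUPR equals average precision when scores are tie-free
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  ap <- mean((cumsum(y) / seq_along(y))[y == 1])
  expect_equal(m$aupr, ap, tolerance = 1e-10)
})

test_that("confusion-matrix metrics respect the 0.5 threshold", {
  scores <- c(0.9, 0.6, 0.4, 0.1, 0.7, 0.2)
  labels <- c(1, 0, 1, 0, 1, 0)
  m <- compute_metrics(scores, labels)
  # predictions: 1,1,0,0,1,0 -> TP=2 FP=1 TN=2 FN=1
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$f1, 2 / 3)
})

test_that("cross-validation builds leak-free test sets at the task ratio", {
  d <- synth_generate(synth_config(M = 15L, N = 24L, n_blocks = 2L,
                                   seed = 9L))
  Sm <- normalize_similarity(similarity_matrix(kmer_features(d$mirna_seqs)))
  Sn <- normalize_similarity(similarity_matrix(kmer_features(d$target_seqs)))
  cfg <- gcn_config(embed_dim = 4, n_layers = 2)
  for (task in c("balanced", "unbalanced")) {
    ratio <- if (task == "balanced") 1 else 20
    n_pos <- sum(d$A)
    if (ratio * ceiling(n_pos / 5) > sum(d$A == 0)) next
    cv <- cross_validate(d$A, Sm, Sn, task = task, strategy = "SCT",
                         n_folds = 5, seeds = 1, config = cfg, epochs = 15)
    expect_equal(cv$per_fold$n_test_neg, ratio * cv$per_fold$n_test_pos)
    expect_equal(sum(cv$per_fold$n_test_pos), n_pos)
    # summary equals the mean of the per-fold reports
    expect_equal(cv$summary$mean[cv$summary$metric == "auc"],
                 mean(cv$per_fold$auc), tolerance = 1e-12)
  }
})

test_that("distinct CV seeds give distinct but valid folds", {
  f1 <- make_folds(100, 5, seed = 1)
  f2 <- make_folds(100, 5, seed = 2)
  expect_false(identical(f1, f2))
  expect_equal(sort(unlist(f1)), 1:100)
  expect_equal(sort(unlist(f2)), 1:100)
})

test_that("cv report serialization round-trips fold metrics", {
  d <- synth_generate(synth_config(M = 12L, N = 18L, n_blocks = 2L,
                                   seed = 21L))
  Sm <- normalize_similarity(similarity_matrix(kmer_features(d$mirna_seqs)))
  Sn <- normalize_similarity(similarity_matrix(kmer_features(d$target_seqs)))
  cv <- cross_validate(d$A, Sm, Sn, n_folds = 2, seeds = 1,
                       config = gcn_config(embed_dim = 4, n_layers = 2),
                       epochs = 10)
  out <- write_cv_report(cv, file.path(withr::local_tempdir(), "eval"))
  tab <- read.delim(out)
  expect_true(all(c("seed", "fold", "metric", "value") %in% names(tab)))
  expect_equal(tab$value[tab$metric == "auc" & tab$fold == 1][1],
               cv$per_fold$auc[1])
  expect_true("auc_mean" %in% tab$metric)
})
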