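test_that("weighted cross-entropy matches hand arithmetic on the 2x2 case", {
  A <- matrix(c(1, 0, 0, 0), 2, 2)
  scores <- matrix(0.5, 2, 2)
  pos <- positive_pairs(A)
  neg <- which(A == 0)
  neg <- cbind(((neg - 1) %% 2) + 1, ((neg - 1) %/% 2) + 1)
  # lambda = 3; loss = -(3*log(.5) + 3*log(.5)) / 4 = 6*log(2)/4
  expect_equal(weighted_cross_entropy(scores, pos, neg), 6 * log(2) / 4,
               tolerance = 1e-12)
})

test_that("perfect scores drive the loss toward zero and order is irrelevant", {
  A <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3)
  pos <- positive_pairs(A)
  negl <- which(A == 0)
  neg <- cbind(((negl - 1) %% 2) + 1, ((negl - 1) %/% 2) + 1)
  eps <- 1e-9
  scores <- matrix(eps, 2, 3)
  scores[pos] <- 1 - eps
  expect_lt(weighted_cross_entropy(scores, pos, neg), 1e-7)

  set.seed(2)
  scores2 <- matrix(runif(6, 0.1, 0.9), 2, 3)
  o <- sample(nrow(neg))
  expect_equal(weighted_cross_entropy(scores2, pos, neg),
               weighted_cross_entropy(scores2, pos[c(2, 1), ], neg[o, ]),
               tolerance = 1e-15)
})

test_that("loss equals an independent per-pair summation oracle", {
  set.seed(13)
  for (rep in 1:5) {
    A <- matrix(rbinom(20, 1, 0.4), 4, 5)
    if (sum(A) == 0 || sum(A) == 20) next
    scores <- matrix(runif(20, 0.05, 0.95), 4, 5)
    pos <- positive_pairs(A)
    negl <- which(A == 0)
    neg <- cbind(((negl - 1) %% 4) + 1, ((negl - 1) %/% 4) + 1)
    lam <- nrow(neg) / nrow(pos)
    acc <- 0
    for (r in seq_len(nrow(pos)))
      acc <- acc + lam * log(scores[pos[r, 1], pos[r, 2]])
    for (r in seq_len(nrow(neg)))
      acc <- acc + log(1 - scores[neg[r, 1], neg[r, 2]])
    expect_equal(weighted_cross_entropy(scores, pos, neg), -acc / 20,
                 tolerance = 1e-10)
  }
})

test_that("empty positive or negative sets are rejected", {
  scores <- matrix(0.5, 2, 2)
  expect_error(weighted_cross_entropy(scores, matrix(0, 0, 2),
                                      cbind(1, 1)), "positive set is empty")
  expect_error(weighted_cross_entropy(scores, cbind(1, 1),
                                      matrix(0, 0, 2)), "negative set is empty")
})

test_that("xavier initialization respects bounds, seed and variance", {
  set.seed(77); W <- xavier_init(100, 100)
  b <- sqrt(6 / 200)
  expect_true(all(abs(W) <= b))
  set.seed(77); W2 <- xavier_init(100, 100)
  expect_identical(W, W2)
  expect_lt(abs(var(as.vector(W)) - 2 / 200), 0.2 * 2 / 200)
})

test_that("cyclic learning rate sweeps the triangular schedule", {
  expect_equal(cyclic_lr(0), 0.01)
  expect_equal(cyclic_lr(50), 0.1)   # mid-cycle peak
  lrs <- vapply(0:499, cyclic_lr, 0)
  expect_equal(min(lrs), 0.01)
  expect_equal(max(lrs), 0.1)
  expect_true(all(lrs >= 0.01 & lrs <= 0.1))
  # constant schedule when bounds coincide
  expect_equal(cyclic_lr(37, 0.01, 0.01), 0.01)
})

test_that("lambda equals the exact unobserved-to-positive pair ratio", {
  st <- tiny_model_setup(M = 8, N = 10, seed = 50)
  pos <- positive_pairs(st$A)
  test_pos <- pos[1:2, , drop = FALSE]
  Am <- mask_test_edges(st$A, test_pos)
  fit <- gcn_link_fit(Am, st$Sm, st$Sn, epochs = 2,
                      config = gcn_config(embed_dim = 4, n_layers = 2),
                      exclude = test_pos, seed = 1)
  n_pos <- sum(Am)
  n_neg <- 80 - n_pos - 2   # all pairs minus train positives minus excluded
  expect_equal(fit$lambda, n_neg / n_pos)
})

test_that("training descends on a planted fixture and is seed-reproducible", {
  d <- synth_generate(synth_config(M = 20L, N = 30L, n_blocks = 2L,
                                   seed = 3L))
  Sm <- normalize_similarity(similarity_matrix(kmer_features(d$mirna_seqs)))
  Sn <- normalize_similarity(similarity_matrix(kmer_features(d$target_seqs)))
  cfg <- gcn_config(embed_dim = 8, node_dropout = 0, edge_dropout = 0)
  fit <- gcn_link_fit(d$A, Sm, Sn, config = cfg, epochs = 120, seed = 7)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])

  fit2 <- gcn_link_fit(d$A, Sm, Sn, config = cfg, epochs = 120, seed = 7)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  fit3 <- gcn_link_fit(d$A, Sm, Sn, config = cfg, epochs = 120, seed = 8)
  expect_false(identical(fit$loss_trace, fit3$loss_trace))
})

test_that("descent is near-monotone on a single-layer no-dropout toy", {
  # mu = 0 bipartite graph, one conv layer, constant learning rate
  d <- synth_generate(synth_config(M = 12L, N = 18L, n_blocks = 2L,
                                   seed = 5L))
  Sm <- normalize_similarity(similarity_matrix(kmer_features(d$mirna_seqs)))
  Sn <- normalize_similarity(similarity_matrix(kmer_features(d$target_seqs)))
  fit <- gcn_link_fit(d$A, Sm, Sn, mu = 0,
                      config = gcn_config(embed_dim = 4, n_layers = 1,
                                          node_dropout = 0,
                                          edge_dropout = 0),
                      epochs = 150, lr_low = 0.01, lr_high = 0.01, seed = 2)
  tr <- fit$loss_trace
  ups <- diff(tr)[diff(tr) > 0]
  # Adam allows transient upticks; the descent must dominate them
  expect_lt(tail(tr, 1), tr[1])
  expect_lt(sum(ups), 0.1 * (tr[1] - tail(tr, 1)))
})

test_that("dropout masks are drawn from the seeded generator", {
  st <- tiny_model_setup(M = 10, N = 14, seed = 60)
  cfg <- gcn_config(embed_dim = 4, n_layers = 2,
                    node_dropout = 0.5, edge_dropout = 0.5)
  f1 <- gcn_link_fit(st$A, st$Sm, st$Sn, config = cfg, epochs = 30, seed = 9)
  f2 <- gcn_link_fit(st$A, st$Sm, st$Sn, config = cfg, epochs = 30, seed = 9)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params, f2$params)
})

test_that("fit object methods expose the expected structure", {
  st <- tiny_model_setup(M = 6, N = 8, seed = 70)
  fit <- gcn_link_fit(st$A, st$Sm, st$Sn, epochs = 10,
                      config = gcn_config(embed_dim = 4, n_layers = 2),
                      seed = 3)
  expect_s3_class(fit, "gcn_link")
  expect_output(print(fit), "link predictor")
  expect_output(print(summary(fit)), "lambda")
  expect_equal(coef(fit, "attention"), fit$attention)
  expect_equal(dim(fitted(fit)), c(6, 8))
  expect_equal(sum(fit$attention), 1, tolerance = 1e-12)

  ranked <- predict(fit, type = "ranked")
  expect_equal(nrow(ranked), sum(st$A == 0))
  expect_true(!is.unsorted(rev(ranked$score)))
  pair_scores <- predict(fit, newdata = cbind(c(1, 2), c(1, 1)))
  expect_equal(pair_scores, fit$fitted_scores[cbind(c(1, 2), c(1, 1))])

  r <- residuals(fit)
  expect_equal(r, st$A - fitted(fit), ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% c(0, 1)))
})
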