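test_that("link split removes the target count and keeps the train graph connected", {
  k4 <- toy_fixture("k4")
  # the complete graph has no non-edges, which the split reports
  expect_message(split <- link_prediction_split(k4, 0.5, seed = 3),
                 "non-edges available")
  expect_equal(nrow(split$pos_edges), 3)
  expect_equal(edge_count(split$train_graph), 3)
  expect_true(igraph::is_connected(as_igraph(split$train_graph)))
  # removed + retained = original edge set
  orig <- caembed:::edge_matrix(k4)
  retained <- caembed:::edge_matrix(split$train_graph)
  recon <- rbind(retained, split$pos_edges)
  expect_equal(sort_pairs(recon), sort_pairs(orig), ignore_attr = TRUE)

  # a sparser graph: negatives match positives in count and avoid edges
  sim <- attributed_sbm(sbm_spec(n = 40, num_blocks = 2, p_in = 0.5,
                                 p_out = 0.15, f = 0, seed = 8))
  sp <- link_prediction_split(sim$graph, 0.5, seed = 2)
  expect_equal(nrow(sp$neg_edges), nrow(sp$pos_edges))
  expect_true(all(sim$graph$A[sp$neg_edges] == 0))
  expect_true(igraph::is_connected(as_igraph(sp$train_graph)))
  expect_equal(edge_count(sp$train_graph) + nrow(sp$pos_edges),
               edge_count(sim$graph))
})

test_that("link split errors when connectivity blocks the removal target", {
  # 6-cycle: only one edge can go before the remainder drops below a tree
  expect_error(link_prediction_split(toy_fixture("cycle6"), 0.5, seed = 1),
               "achieved 1")
  # every edge of a tree is a bridge
  expect_error(link_prediction_split(toy_fixture("star"), 0.3, seed = 1),
               "achieved 0")
  # disconnected input is rejected outright
  expect_error(link_prediction_split(toy_fixture("two_triangles"), 0.5, seed = 1),
               "connected")
})

test_that("ranking AUC matches the pair-counting oracle and edge cases", {
  # engineered embeddings with prescribed pairwise cosine ranking:
  # 1-dim positive embeddings give all-equal scores -> AUC 1/2
  Yc <- matrix(c(1, 2, 3, 4), 4, 1)
  split <- list(pos_edges = cbind(1, 2), neg_edges = cbind(3, 4))
  expect_equal(auc_ranking(Yc, split), 0.5)
  # oracle on random scores via the internal score-free route
  set.seed(10)
  pos <- round(runif(7), 2)
  neg <- round(runif(9), 2)
  expect_equal(caembed:::auc_from_scores(pos, neg), brute_auc(pos, neg))
  expect_equal(caembed:::auc_from_scores(c(0.9, 0.5), c(0.7, 0.1)), 0.75)
  expect_equal(caembed:::auc_from_scores(c(3, 4), c(1, 2)), 1)
  # Mann-Whitney U cross-check
  u <- wilcox.test(pos, neg, exact = FALSE)$statistic
  expect_equal(caembed:::auc_from_scores(pos, neg),
               unname(u) / (length(pos) * length(neg)))
})

test_that("zero embedding vectors score 0 with a message", {
  Y <- rbind(c(0, 0), c(1, 0), c(1, 1))
  split <- list(pos_edges = cbind(1, 2), neg_edges = cbind(2, 3))
  # pos pair touches the zero vector -> score 0; neg pair scores ~0.707
  expect_message(a <- auc_ranking(Y, split), "zero embedding")
  expect_equal(a, 0)
})

test_that("node classification is perfect on separated embeddings and chance on noise", {
  # one-hot class embeddings
  lab <- rep(1:3, each = 10)
  Y <- diag(3)[lab, ]
  r <- node_classification_eval(Y, lab, train_frac = 0.3, repeats = 3, seed = 1)
  expect_equal(r$micro_f1, 1)
  expect_equal(r$macro_f1, 1)
  # labels independent of the embedding: micro-F1 near 1/2 for 2 balanced classes
  set.seed(2)
  Yr <- matrix(rnorm(200 * 4), 200, 4)
  labr <- rep(1:2, each = 100)
  rr <- node_classification_eval(Yr, labr, train_frac = 0.3, repeats = 10, seed = 3)
  expect_lt(abs(rr$micro_f1 - 0.5), 0.12)
  expect_error(node_classification_eval(Y, rep(1, 30)), "two classes")
})

test_that("F1 formulas reproduce the hand-computed confusion table", {
  # 2-class table: TP=3, FP=1, FN=1, TN=5 for the positive class
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  f1 <- caembed:::f1_scores(truth, pred, positive = "pos")
  expect_equal(f1$positive_f1, 0.75)
  # micro over instances equals accuracy for single-label data
  f1m <- caembed:::f1_scores(truth, pred)
  expect_equal(f1m$micro, 0.8)
  expect_equal(f1m$macro, mean(c(0.75, 2 * 5 / (10 + 1 + 1))))
})

test_that("NMI behaves as an information metric", {
  a <- rep(1:3, each = 5)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(rep(7, 5), rep(2, 5), rep(5, 5))), 1)  # relabeling
  expect_equal(nmi(rep(1, 10), rep(1, 10)), 1)                 # degenerate
  set.seed(4)
  x <- sample(rep(1:2, each = 500))
  y <- sample(rep(1:2, each = 500))
  expect_lt(nmi(x, y), 0.02)
  # cross-check against the igraph implementation
  for (rep in 1:3) {
    p1 <- sample(1:4, 60, replace = TRUE)
    p2 <- sample(1:3, 60, replace = TRUE)
    expect_equal(nmi(p1, p2), igraph::compare(p1, p2, method = "nmi"),
                 tolerance = 1e-12)
  }
  expect_error(nmi(1:3, 1:4), "different node sets")
})
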