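test_that("label propagation separates disconnected components and merges cliques", {
  two_tri <- toy_fixture("two_triangles")
  p <- lpa(two_tri, seed = 1)
  expect_equal(p$l, 2)
  expect_equal(p$membership[1:3], rep(p$membership[1], 3))
  expect_equal(p$membership[4:6], rep(p$membership[4], 3))

  k5 <- attributed_graph({A <- matrix(1, 5, 5); diag(A) <- 0; A})
  for (s in 1:5) expect_equal(lpa(k5, seed = s)$l, 1)

  # isolated node keeps its own label
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[1, 3] <- 1; A <- A + t(A)
  p <- lpa(attributed_graph(A), seed = 2)
  expect_equal(p$l, 2)
  expect_false(p$membership[4] %in% p$membership[1:3])
})

test_that("label propagation never merges disconnected components", {
  set.seed(42)
  for (rep in 1:5) {
    sim <- attributed_sbm(sbm_spec(n = 40, num_blocks = 2, p_in = 0.5, p_out = 0,
                                   f = 0, seed = rep))
    g <- sim$graph
    comp <- igraph::components(as_igraph(g))$membership
    p <- lpa(g, seed = rep)
    # a community may not span two components
    expect_true(all(tapply(comp, p$membership, function(x) length(unique(x))) == 1))
  }
})

test_that("lpa and multilevel are reproducible under a fixed seed", {
  sim <- attributed_sbm(sbm_spec(n = 60, num_blocks = 3, p_in = 0.4, p_out = 0.05,
                                 f = 0, seed = 3))
  expect_identical(lpa(sim$graph, seed = 9)$membership,
                   lpa(sim$graph, seed = 9)$membership)
  expect_identical(multilevel(sim$graph, seed = 9)$membership,
                   multilevel(sim$graph, seed = 9)$membership)
})

test_that("modularity matches hand-derived and brute-force values", {
  two_tri <- toy_fixture("two_triangles")
  expect_equal(graph_modularity(two_tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  # one community: zero by construction
  expect_equal(graph_modularity(two_tri, rep(1, 6)), 0)
  # 4-cycle split into opposite pairs
  c4 <- attributed_graph(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                               c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_equal(graph_modularity(c4, c(1, 1, 2, 2)), 0)
  expect_error(graph_modularity(attributed_graph(diag(0, 3)), c(1, 2, 3)), "edgeless")
})

test_that("modularity agrees with the brute-force double loop and igraph", {
  set.seed(11)
  for (rep in 1:5) {
    sim <- attributed_sbm(sbm_spec(n = sample(10:30, 1), num_blocks = 2,
                                   p_in = 0.5, p_out = 0.2, f = 0, seed = rep))
    g <- sim$graph
    if (edge_count(g) == 0) next
    memb <- sample(1:3, g$n, replace = TRUE)
    q <- graph_modularity(g, memb)
    expect_equal(q, brute_modularity(g, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(as_igraph(g), memb), tolerance = 1e-12)
  }
})

test_that("multilevel recovers planted structure on the toy fixtures", {
  two_tri <- toy_fixture("two_triangles")
  p <- multilevel(two_tri, seed = 1)
  expect_equal(p$l, 2)
  expect_equal(graph_modularity(two_tri, p), 0.5)

  tri <- attributed_graph(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_equal(multilevel(tri, seed = 1)$l, 1)

  bb <- toy_fixture("barbell")
  p <- multilevel(bb, seed = 1)
  expect_equal(p$l, 2)
  expect_equal(p$membership[1:5], rep(p$membership[1], 5))
  expect_equal(p$membership[6:10], rep(p$membership[6], 5))

  expect_error(multilevel(attributed_graph(diag(0, 2))), "at least one edge")
})

test_that("multilevel modularity beats the singleton partition and never drops per pass", {
  set.seed(5)
  for (rep in 1:4) {
    sim <- attributed_sbm(sbm_spec(n = 50, num_blocks = 2, p_in = 0.3, p_out = 0.05,
                                   f = 0, seed = rep + 20))
    g <- sim$graph
    p <- multilevel(g, seed = rep)
    q_single <- graph_modularity(g, seq_len(g$n))
    expect_gte(graph_modularity(g, p), q_single)
    qs <- attr(p, "q_per_pass")
    expect_true(all(diff(qs) >= -1e-12))
    expect_equal(qs[length(qs)], graph_modularity(g, p), tolerance = 1e-12)
  }
})

test_that("multilevel is competitive with the igraph reference on random graphs", {
  set.seed(13)
  for (rep in 1:3) {
    sim <- attributed_sbm(sbm_spec(n = 60, num_blocks = 3, p_in = 0.3, p_out = 0.02,
                                   f = 0, seed = rep + 40))
    g <- sim$graph
    q_ours <- graph_modularity(g, multilevel(g, seed = rep))
    q_ref <- igraph::modularity(igraph::cluster_louvain(as_igraph(g)))
    expect_gte(q_ours, q_ref - 0.05)
  }
})

test_that("external assignments load with first-appearance compaction", {
  g <- read_edge_list(write_tmp(c("0 1", "1 2")))
  p <- load_assignment(write_tmp(c("0 A", "1 A", "2 B")), g)
  expect_equal(p$membership, c(1, 1, 2))
  expect_equal(p$l, 2)
  expect_equal(as.matrix(p$C), rbind(c(1, 0), c(1, 0), c(0, 1)), ignore_attr = TRUE)
  expect_error(load_assignment(write_tmp(c("0 A", "1 A")), g), "missing node '2'")
  expect_error(load_assignment(write_tmp(c("0 x", "0 y", "1 x", "2 x")), g),
               "overlapping")
  # repeats with the same token are fine
  p2 <- load_assignment(write_tmp(c("0 x", "0 x", "1 x", "2 y")), g)
  expect_equal(p2$membership, c(1, 1, 2))
})

test_that("community size report summarizes the partition", {
  r <- community_size_report(community_assignment(c(1, 1, 1, 2)))
  expect_equal(r$l, 2)
  expect_equal(r$sizes, c(3, 1))
  expect_equal(r$largest_fraction, 0.75)
  expect_equal(community_size_report(community_assignment(rep(1, 5)))$largest_fraction, 1)
  expect_equal(community_size_report(community_assignment(1:10))$largest_fraction, 0.1)
  expect_equal(sum(r$sizes), 4)
})

test_that("one-hot indicator matrix C encodes the membership", {
  p <- community_assignment(c(2, 2, 7, 2))
  expect_equal(p$l, 2)
  expect_equal(Matrix::rowSums(p$C), rep(1, 4), ignore_attr = TRUE)
  expect_equal(which(as.matrix(p$C)[3, ] == 1), 2)
})
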