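#' Specification of a planted-partition attributed graph
#'
#' Balanced stochastic block model with community-correlated binary
#' attributes: the attribute set is divided evenly among the blocks,
#' and a node switches on its own block's attributes with probability
#' `attr_signal` and every other attribute with probability
#' `attr_noise`.
#'
#' @param n node count.
#' @param num_blocks number of planted blocks; block sizes are balanced,
#'   with remainder nodes joining the last block.
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability, `p_out < p_in`.
#' @param f total number of binary attributes (0 for structure-only).
#' @param attr_signal on-probability of a node's own-block attributes.
#' @param attr_noise on-probability of other blocks' attributes,
#'   `attr_noise < attr_signal`.
#' @param seed integer seed.
#' @return an `sbm_spec` list.
#' @export
sbm_spec <- function(n = 300L, num_blocks = 3L, p_in = 0.1, p_out = 0.005,
                     f = 60L, attr_signal = 0.3, attr_noise = 0.02,
                     seed = 1L) {
  stopifnot(n >= num_blocks, num_blocks >= 1,
            p_out >= 0, p_out < p_in, p_in <= 1)
  if (f > 0) stopifnot(attr_noise >= 0, attr_noise < attr_signal, attr_signal <= 1)
  structure(list(n = as.integer(n), num_blocks = as.integer(num_blocks),
                 p_in = p_in, p_out = p_out, f = as.integer(f),
                 attr_signal = attr_signal, attr_noise = attr_noise,
                 seed = as.integer(seed)),
            class = "sbm_spec")
}

#' Generate an attributed stochastic block model graph
#'
#' Every unordered within-block node pair is an edge with probability
#' `p_in`, every between-block pair with `p_out`; attributes follow the
#' block-correlated Bernoulli scheme of [sbm_spec()]. Node labels are
#' the planted block ids.
#'
#' @param spec an [sbm_spec()].
#' @return list with `graph` (an `attributed_graph`, labels = blocks)
#'   and `truth` (the planted `community_assignment`).
#' @export
attributed_sbm <- function(spec = sbm_spec()) {
  n <- spec$n
  k <- spec$num_blocks
  base <- n %/% k
  block <- rep(seq_len(k), times = c(rep(base, k - 1), n - base * (k - 1)))
  with_seed(spec$seed, {
    iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- block[iu[, 1]] == block[iu[, 2]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    on <- stats::runif(nrow(iu)) < p
    A <- Matrix::sparseMatrix(
      i = c(iu[on, 1], iu[on, 2]), j = c(iu[on, 2], iu[on, 1]),
      x = 1, dims = c(n, n)
    )
    X <- NULL
    if (spec$f > 0) {
      fb <- spec$f %/% k
      attr_block <- rep(seq_len(k), times = c(rep(fb, k - 1), spec$f - fb * (k - 1)))
      own <- outer(block, attr_block, `==`)
      P <- ifelse(own, spec$attr_signal, spec$attr_noise)
      X <- matrix(as.numeric(stats::runif(n * spec$f) < P), n, spec$f)
    }
    graph <- attributed_graph(A, X = X, labels = block)
    list(graph = graph, truth = community_assignment(block))
  })
}

#' Deterministic toy graphs used throughout the tests
#'
#' @param name one of `"two_triangles"` (two disjoint 3-cliques),
#'   `"barbell"` (two 5-cliques joined by one edge), `"k4"`, `"cycle6"`,
#'   `"star"` (one hub with 5 leaves).
#' @return an `attributed_graph`.
#' @export
toy_fixture <- function(name = c("two_triangles", "barbell", "k4", "cycle6", "star")) {
  name <- match.arg(name)
  edges <- switch(
    name,
    two_triangles = rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    barbell = {
      k5a <- t(utils::combn(1:5, 2))
      k5b <- t(utils::combn(6:10, 2))
      rbind(k5a, k5b, c(5, 6))
    },
    k4 = t(utils::combn(1:4, 2)),
    cycle6 = cbind(1:6, c(2:6, 1)),
    star = cbind(1L, 2:6)
  )
  n <- max(edges)
  A <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n)
  )
  attributed_graph(A)
}

#' Write a generated graph to plain-text files
#'
#' Emits `<prefix>.edgelist`, and where present `<prefix>.attr`
#' (dense rows keyed by node id) and `<prefix>.labels`, all in the
#' formats [read_edge_list()], [read_attribute_matrix()] and
#' [read_labels()] read back. Isolated nodes are not representable in
#' an edge list and are therefore absent from the round trip.
#'
#' @param graph an `attributed_graph`.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_graph_files <- function(graph, prefix) {
  el <- edge_matrix(graph)
  files <- paste0(prefix, ".edgelist")
  writeLines(paste(graph$node_ids[el[, 1]], graph$node_ids[el[, 2]]), files)
  if (!is.null(graph$X)) {
    f <- paste0(prefix, ".attr")
    writeLines(paste(graph$node_ids,
                     apply(graph$X, 1, paste, collapse = " ")), f)
    files <- c(files, f)
  }
  if (!is.null(graph$labels)) {
    f <- paste0(prefix, ".labels")
    keep <- !is.na(graph$labels)
    writeLines(paste(graph$node_ids[keep], graph$labels[keep]), f)
    files <- c(files, f)
  }
  invisible(files)
}
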