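#' Random-walk and negative-sampling configuration
#'
#' Defaults follow common practice for walk-based embedding: 10 walks
#' per node of length 80, window 10, 10 negative samples, and unbiased
#' walks (`p = q = 1`).
#'
#' @param walks_per_node walks started at every node (r).
#' @param walk_length maximum walk length in nodes.
#' @param window skip-gram context window half-width (b).
#' @param num_negatives negative samples per (center, context) pair.
#' @param p return parameter of the second-order walk bias.
#' @param q in-out parameter of the second-order walk bias.
#' @param seed integer seed for walk generation.
#' @return a `walk_config` list.
#' @export
walk_config <- function(walks_per_node = 10L, walk_length = 80L, window = 10L,
                        num_negatives = 10L, p = 1, q = 1, seed = 1L) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, window >= 1,
            num_negatives >= 1, p > 0, q > 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 num_negatives = as.integer(num_negatives),
                 p = p, q = q, seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate random walks over a graph
#'
#' Starts `walks_per_node` walks at every node and extends each up to
#' `walk_length` nodes. With `p = q = 1` transitions are uniform over
#' neighbors (first-order, fully vectorized); otherwise the second-order
#' bias applies: stepping from `v` with predecessor `t`, a candidate `x`
#' is weighted `1/p` if `x = t`, `1` if `x` is adjacent to `t`, and
#' `1/q` otherwise. Walks truncate at dead ends, so isolated nodes give
#' length-1 walks.
#'
#' @param graph an `attributed_graph`.
#' @param config a [walk_config()].
#' @param seed optional override of `config$seed`.
#' @return list of integer node-index vectors, `walks_per_node * n` of
#'   them.
#' @export
generate_walks <- function(graph, config = walk_config(), seed = NULL) {
  if (graph$n < 1L) stop("graph has no nodes", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  nbrs <- neighbor_list(graph)
  deg <- lengths(nbrs)
  n <- graph$n
  L <- config$walk_length
  with_seed(seed, {
    starts <- unlist(lapply(seq_len(config$walks_per_node), function(.) sample.int(n)))
    if (config$p == 1 && config$q == 1) {
      flat <- unlist(nbrs, use.names = FALSE)
      ptr <- c(0L, cumsum(deg))
      nw <- length(starts)
      W <- matrix(NA_integer_, nw, L)
      W[, 1] <- starts
      cur <- starts
      alive <- deg[cur] > 0L
      t <- 1L
      while (t < L && any(alive)) {
        idx <- which(alive)
        d <- deg[cur[idx]]
        pick <- ptr[cur[idx]] + sample_int_vec(d)
        nxt <- flat[pick]
        cur[idx] <- nxt
        W[cbind(idx, t + 1L)] <- nxt
        alive[idx] <- deg[nxt] > 0L
        t <- t + 1L
      }
      lapply(seq_len(nw), function(i) W[i, !is.na(W[i, ])])
    } else {
      lapply(starts, function(s) biased_walk(s, nbrs, L, config$p, config$q))
    }
  })
}

# one uniform draw from 1..k for each element of the integer vector k
sample_int_vec <- function(k) {
  pmin(floor(stats::runif(length(k)) * k) + 1L, k)
}

biased_walk <- function(start, nbrs, L, p, q) {
  walk <- integer(L)
  walk[1] <- start
  if (length(nbrs[[start]]) == 0L || L == 1L) return(walk[1])
  walk[2] <- sample_one(nbrs[[start]])
  if (L == 2L) return(walk)
  for (t in 2:(L - 1)) {
    v <- walk[t]; prev <- walk[t - 1]
    cand <- nbrs[[v]]
    if (length(cand) == 0L) return(walk[seq_len(t)])
    w <- ifelse(cand == prev, 1 / p,
                ifelse(cand %in% nbrs[[prev]], 1, 1 / q))
    walk[t + 1] <- cand[sample.int(length(cand), 1L, prob = w)]
  }
  walk
}

# sample() on a length-1 vector would treat it as 1:x; avoid that trap
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Enumerate skip-gram context pairs from walks
#'
#' For every position `i` of every walk, pairs the center node `w_i`
#' with `w_(i+j)` for all offsets `0 < |j| <= window` that stay inside
#' the walk.
#'
#' @param walks list of integer node-index vectors.
#' @param window context window half-width (b >= 1).
#' @return integer matrix with columns `center` and `context`, one row
#'   per ordered pair (row order unspecified).
#' @export
context_pairs <- function(walks, window) {
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  out <- lapply(walks, function(w) {
    len <- length(w)
    if (len < 2L) return(NULL)
    js <- seq_len(min(window, len - 1L))
    ctr <- unlist(lapply(js, function(j) c(w[seq_len(len - j)], w[(1 + j):len])))
    ctx <- unlist(lapply(js, function(j) c(w[(1 + j):len], w[seq_len(len - j)])))
    cbind(ctr, ctx)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("center", "context")
  out
}

#' Build an alias table for O(1) categorical sampling
#'
#' Vose's alias method: preprocessing is O(K), every subsequent draw
#' costs one uniform for the bucket and one for the coin flip.
#'
#' @param probs nonnegative weights (need not be normalized).
#' @return an `alias_table` list with `prob` and `alias` vectors.
#' @export
alias_table <- function(probs) {
  if (any(probs < 0) || all(probs == 0)) {
    stop("alias_table needs nonnegative weights with at least one positive", call. = FALSE)
  }
  K <- length(probs)
  p <- probs / sum(probs) * K
  alias <- integer(K)
  prob <- numeric(K)
  small <- which(p < 1)
  large <- which(p >= 1)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    prob[s] <- p[s]
    alias[s] <- l
    p[l] <- p[l] + p[s] - 1
    if (p[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  prob[c(small, large)] <- 1
  alias[c(small, large)] <- c(small, large)
  structure(list(prob = prob, alias = alias), class = "alias_table")
}

#' Draw from an alias table
#'
#' @param table an [alias_table()].
#' @param num number of i.i.d. draws.
#' @return integer vector of category indices.
#' @export
alias_draw <- function(table, num) {
  K <- length(table$prob)
  i <- pmin(floor(stats::runif(num) * K) + 1L, K)
  u <- stats::runif(num)
  ifelse(u < table$prob[i], i, table$alias[i])
}

#' Degree-biased noise sampler for negative sampling
#'
#' Draws noise nodes i.i.d. with \eqn{P(v) \propto d_v^{3/4}}, the
#' flattened-unigram distribution standard in skip-gram training, using
#' an alias table so each draw is O(1). Zero-degree nodes are never
#' drawn.
#'
#' @param degs per-node degree counts; at least one must be positive.
#' @param num number of draws.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return integer vector of node indices.
#' @export
negative_sample <- function(degs, num, seed = NULL) {
  tab <- negative_sampler_table(degs)
  with_seed(seed, alias_draw(tab, num))
}

# alias table over the d^(3/4) noise distribution
negative_sampler_table <- function(degs) {
  if (all(degs == 0)) stop("all degrees are zero: noise distribution undefined", call. = FALSE)
  alias_table(degs^0.75)
}
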