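#' Construct a community assignment
#'
#' Wraps a per-node membership vector into the package's community
#' container. Membership tokens are compacted to contiguous integer ids
#' `1..l` in first-appearance order (by node index).
#'
#' @param membership vector (integer or character) with one community
#'   token per node.
#' @return an object of class `community_assignment`: list with
#'   `membership` (integer `1..l`), `l` (community count) and `C`
#'   (sparse `n x l` one-hot indicator matrix).
#' @export
community_assignment <- function(membership) {
  if (length(membership) < 1L) stop("empty membership", call. = FALSE)
  if (anyNA(membership)) stop("membership contains NA", call. = FALSE)
  comp <- match(membership, unique(membership))
  l <- max(comp)
  n <- length(comp)
  C <- Matrix::sparseMatrix(i = seq_len(n), j = comp, x = 1, dims = c(n, l))
  structure(list(membership = comp, l = l, C = C),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community_assignment: %d nodes in %d communities\n",
              length(x$membership), x$l))
  invisible(x)
}

# neighbor list: element i = integer vector of neighbors of node i
neighbor_list <- function(graph) {
  A <- graph$A
  n <- graph$n
  cnt <- diff(A@p)
  unname(split(A@i + 1L, factor(rep.int(seq_len(n), cnt), levels = seq_len(n))))
}

#' Label propagation community detection
#'
#' Asynchronous label propagation: every node starts with a unique label;
#' nodes are then visited in a fresh seeded random order each sweep and
#' adopt the most frequent label among their neighbors, ties broken
#' uniformly at random. The sweep loop stops when every node's label is
#' one of its neighborhood's modal labels, or after `max_iter` sweeps.
#' Isolated nodes keep their own label.
#'
#' @param graph an `attributed_graph` with at least one node.
#' @param seed integer seed controlling visit order and tie-breaks.
#' @param max_iter maximum number of full sweeps (default 100).
#' @return a `community_assignment`.
#' @export
lpa <- function(graph, seed = 1L, max_iter = 100L) {
  if (graph$n < 1L) stop("graph has no nodes", call. = FALSE)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  nbrs <- neighbor_list(graph)
  n <- graph$n
  with_seed(seed, {
    lab <- seq_len(n)
    for (iter in seq_len(max_iter)) {
      for (v in sample.int(n)) {
        nb <- nbrs[[v]]
        if (length(nb) == 0L) next
        tab <- tabulate(lab[nb], nbins = n)
        modes <- which(tab == max(tab))
        lab[v] <- if (length(modes) == 1L) modes else modes[sample.int(length(modes), 1L)]
      }
      stable <- all(vapply(seq_len(n), function(v) {
        nb <- nbrs[[v]]
        if (length(nb) == 0L) return(TRUE)
        tab <- tabulate(lab[nb], nbins = n)
        tab[lab[v]] == max(tab)
      }, logical(1)))
      if (stable) break
    }
    community_assignment(lab)
  })
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left(a_{ij} -
#'   \frac{d_i d_j}{2m}\right)\delta(c_i, c_j)}
#' computed per community as \eqn{\sum_c (e_c/m - (d_c/2m)^2)} where
#' \eqn{e_c} is the number of within-community edges and \eqn{d_c} the
#' total degree of community \eqn{c}.
#'
#' @param graph an `attributed_graph` with at least one edge.
#' @param assignment a `community_assignment` (or plain membership
#'   vector) covering all nodes.
#' @return modularity value in `[-0.5, 1]`.
#' @export
graph_modularity <- function(graph, assignment) {
  m <- edge_count(graph)
  if (m == 0L) stop("modularity is undefined on an edgeless graph", call. = FALSE)
  memb <- if (inherits(assignment, "community_assignment")) assignment$membership else assignment
  if (length(memb) != graph$n) stop("assignment does not cover all nodes", call. = FALSE)
  el <- edge_matrix(graph)
  e_c <- tabulate(memb[el[, 1]][memb[el[, 1]] == memb[el[, 2]]], nbins = max(memb))
  d_c <- as.vector(tapply(degrees(graph), memb, sum, default = 0))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# one Louvain phase on a weighted graph given as an edge data frame
# (i, j, w with i < j), per-node self-loop weights and total weight m.
# Returns the community vector after local moving.
louvain_phase <- function(n, ei, ej, ew, self_w, m) {
  adj_i <- c(ei, ej)
  adj_j <- c(ej, ei)
  adj_w <- c(ew, ew)
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]; adj_w <- adj_w[ord]
  ptr <- c(0L, cumsum(tabulate(adj_i, nbins = n)))
  k <- numeric(n)
  agg <- tapply(adj_w, factor(adj_i, levels = seq_len(n)), sum, default = 0)
  k <- as.vector(agg) + 2 * self_w
  comm <- seq_len(n)
  sigma_tot <- k
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      lo <- ptr[v] + 1L; hi <- ptr[v + 1L]
      if (hi < lo) next
      nb <- adj_j[lo:hi]
      wv <- adj_w[lo:hi]
      c0 <- comm[v]
      sigma_tot[c0] <- sigma_tot[c0] - k[v]
      nb_comm <- comm[nb]
      k_ic <- tapply(wv, nb_comm, sum)
      cand <- as.integer(names(k_ic))
      if (!(c0 %in% cand)) {
        cand <- c(cand, c0)
        k_ic <- c(k_ic, 0)
      }
      gain <- as.vector(k_ic) / m - sigma_tot[cand] * k[v] / (2 * m * m)
      best <- cand[which.max(gain)]
      g0 <- gain[match(c0, cand)]
      if (best != c0 && max(gain) > g0 + 1e-12) {
        comm[v] <- best
        moved <- TRUE
        sigma_tot[best] <- sigma_tot[best] + k[v]
      } else {
        sigma_tot[c0] <- sigma_tot[c0] + k[v]
      }
    }
    if (!moved) break
  }
  comm
}

#' Two-phase modularity (multilevel) community detection
#'
#' Greedy modularity optimization in the classic two-phase scheme:
#' phase 1 sweeps nodes in a seeded random order, moving each node to
#' the neighboring community with the largest positive modularity gain
#' (incremental \eqn{\Delta Q} bookkeeping) until no move improves;
#' phase 2 contracts communities into super-nodes, keeping integer edge
#' weights, and the two phases repeat until a full pass no longer
#' increases modularity. The modularity after each pass is recorded in
#' the `q_per_pass` attribute of the result.
#'
#' @param graph an `attributed_graph` with at least one edge.
#' @param seed integer seed controlling the node sweep order.
#' @return a `community_assignment` with attribute `q_per_pass`.
#' @export
multilevel <- function(graph, seed = 1L) {
  if (edge_count(graph) == 0L) {
    stop("multilevel requires at least one edge (modularity undefined)", call. = FALSE)
  }
  el <- edge_matrix(graph)
  with_seed(seed, {
    n_cur <- graph$n
    ei <- el[, 1]; ej <- el[, 2]
    ew <- rep(1, nrow(el))
    self_w <- numeric(n_cur)
    m <- sum(ew) + sum(self_w)
    node2comm <- seq_len(graph$n)   # original node -> current flattened community
    q_hist <- numeric(0)
    q_prev <- -Inf
    repeat {
      comm <- louvain_phase(n_cur, ei, ej, ew, self_w, m)
      comm <- match(comm, unique(comm))
      flat <- comm[node2comm]
      q <- graph_modularity(graph, flat)
      if (q <= q_prev + 1e-12) break
      q_hist <- c(q_hist, q)
      q_prev <- q
      node2comm <- flat
      # aggregate to the community graph
      n_new <- max(comm)
      ci <- comm[ei]; cj <- comm[ej]
      inside <- ci == cj
      self_new <- as.vector(tapply(ew[inside], factor(ci[inside], levels = seq_len(n_new)),
                                   sum, default = 0)) +
        as.vector(tapply(self_w, factor(comm, levels = seq_len(n_new)), sum, default = 0))
      bi <- pmin(ci[!inside], cj[!inside])
      bj <- pmax(ci[!inside], cj[!inside])
      bw <- ew[!inside]
      if (length(bi)) {
        key <- paste(bi, bj)
        agg <- tapply(bw, key, sum)
        parts <- strsplit(names(agg), " ")
        ei <- as.integer(vapply(parts, `[`, character(1), 1L))
        ej <- as.integer(vapply(parts, `[`, character(1), 2L))
        ew <- as.vector(agg)
      } else {
        ei <- integer(0); ej <- integer(0); ew <- numeric(0)
      }
      self_w <- self_new
      n_cur <- n_new
      if (n_cur == 1L || length(ei) == 0L) break
    }
    out <- community_assignment(node2comm)
    attr(out, "q_per_pass") <- q_hist
    out
  })
}

#' Load an externally computed community assignment
#'
#' Plug-in slot for external community detectors (e.g. flow-based map
#' methods): a two-column `node community_token` file. Tokens are
#' compacted to contiguous ids in order of first appearance in the file.
#'
#' @param path path to the assignment file.
#' @param graph the `attributed_graph` the assignment refers to; every
#'   graph node must be listed exactly once (repeats with the same token
#'   are tolerated).
#' @return a `community_assignment`.
#' @export
load_assignment <- function(path, graph) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop(sprintf("empty assignment file: %s", path), call. = FALSE)
  toks <- strsplit(trimws(dat$lines), "\\s+")
  if (any(lengths(toks) < 2L)) {
    stop(sprintf("malformed assignment line %d: need 'node community'",
                 dat$lineno[which(lengths(toks) < 2L)[1]]), call. = FALSE)
  }
  node_tok <- vapply(toks, `[`, character(1), 1L)
  comm_tok <- vapply(toks, `[`, character(1), 2L)
  row <- match(node_tok, graph$node_ids)
  if (anyNA(row)) {
    stop(sprintf("assignment file: node '%s' is not in the graph",
                 node_tok[which(is.na(row))[1]]), call. = FALSE)
  }
  comm_id <- match(comm_tok, unique(comm_tok))  # first-appearance compaction
  dup <- duplicated(row)
  if (any(dup)) {
    clash <- row[dup][comm_id[dup] != comm_id[match(row[dup], row)]]
    if (length(clash)) {
      stop(sprintf("overlapping assignment for node '%s'",
                   graph$node_ids[clash[1]]), call. = FALSE)
    }
  }
  membership <- rep(NA_integer_, graph$n)
  membership[row] <- comm_id
  if (anyNA(membership)) {
    stop(sprintf("assignment file is missing node '%s'",
                 graph$node_ids[which(is.na(membership))[1]]), call. = FALSE)
  }
  community_assignment(membership)
}

#' Community size summary
#'
#' Reports the number of communities, their sizes, and the fraction of
#' nodes gathered in the largest community — a useful diagnostic because
#' detectors differ sharply in the scale of the communities they find
#' (a detector that dumps ~90% of a network into one block carries
#' little mesoscopic information).
#'
#' @param assignment a `community_assignment`.
#' @return list with `l`, `sizes` (per community id) and
#'   `largest_fraction`.
#' @export
community_size_report <- function(assignment) {
  sizes <- tabulate(assignment$membership, nbins = assignment$l)
  list(
    l = assignment$l,
    sizes = sizes,
    largest_fraction = max(sizes) / length(assignment$membership)
  )
}
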