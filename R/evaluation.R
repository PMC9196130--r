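embedding_matrix <- function(Y) {
  if (inherits(Y, "node_embedding")) Y$Y else as.matrix(Y)
}

#' Connectivity-preserving link-prediction split
#'
#' Visits edges in a seeded random order and removes an edge only if the
#' remaining training graph stays connected, until `floor(frac * m)`
#' edges are removed. Removed edges are the positive test samples; the
#' same number of node pairs that are non-adjacent in the *original*
#' graph are drawn uniformly without replacement as negatives.
#'
#' @param graph a connected `attributed_graph`.
#' @param frac fraction of edges to remove, in (0, 1); default 0.5.
#' @param seed integer seed for the edge order and negative draws.
#' @return a `link_split`: list with `train_graph` (an
#'   `attributed_graph`), `pos_edges` and `neg_edges` (2-column integer
#'   matrices of internal node indices).
#' @export
link_prediction_split <- function(graph, frac = 0.5, seed = 1L) {
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)", call. = FALSE)
  g <- as_igraph(graph)
  if (!igraph::is_connected(g)) stop("graph must be connected", call. = FALSE)
  el <- edge_matrix(graph)
  m <- nrow(el)
  target <- floor(frac * m)
  if (target < 1L) stop("removal target is zero: graph too small for this `frac`", call. = FALSE)
  with_seed(seed, {
    ord <- sample.int(m)
    removed <- matrix(0L, 0, 2)
    for (e in ord) {
      if (nrow(removed) >= target) break
      eid <- igraph::get_edge_ids(g, el[e, ])
      g2 <- igraph::delete_edges(g, eid)
      if (igraph::is_connected(g2)) {
        g <- g2
        removed <- rbind(removed, el[e, , drop = FALSE])
      }
    }
    if (nrow(removed) < target) {
      stop(sprintf(
        "cannot remove %d edges while keeping the graph connected (achieved %d)",
        target, nrow(removed)
      ), call. = FALSE)
    }
    # negatives: uniform over non-adjacent pairs of the original graph
    n <- graph$n
    max_neg <- n * (n - 1) / 2 - m
    n_neg <- min(target, max_neg)
    if (n_neg < target) {
      message(sprintf(
        "link_prediction_split: only %d non-edges available for %d positives",
        max_neg, target
      ))
    }
    seen <- new.env(hash = TRUE)
    neg <- matrix(0L, 0, 2)
    while (nrow(neg) < n_neg) {
      k <- (n_neg - nrow(neg)) * 2L
      i <- sample.int(n, k, replace = TRUE)
      j <- sample.int(n, k, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo != hi & graph$A[cbind(lo, hi)] == 0
      for (t in which(ok)) {
        key <- paste(lo[t], hi[t])
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          neg <- rbind(neg, c(lo[t], hi[t]))
          if (nrow(neg) >= n_neg) break
        }
      }
    }
    keep <- !(paste(el[, 1], el[, 2]) %in% paste(removed[, 1], removed[, 2]))
    A_train <- Matrix::sparseMatrix(
      i = c(el[keep, 1], el[keep, 2]), j = c(el[keep, 2], el[keep, 1]),
      x = 1, dims = c(n, n)
    )
    train <- attributed_graph(A_train, node_ids = graph$node_ids,
                              X = graph$X, labels = graph$labels)
    structure(list(train_graph = train, pos_edges = removed, neg_edges = neg),
              class = "link_split")
  })
}

cosine_pair_scores <- function(Y, pairs) {
  nrm <- sqrt(rowSums(Y^2))
  s <- rowSums(Y[pairs[, 1], , drop = FALSE] * Y[pairs[, 2], , drop = FALSE])
  denom <- nrm[pairs[, 1]] * nrm[pairs[, 2]]
  zero <- denom == 0
  if (any(zero)) {
    message(sprintf("cosine score: %d pair(s) with a zero embedding scored 0", sum(zero)))
    denom[zero] <- 1
    s[zero] <- 0
  }
  s / denom
}

#' Ranking AUC of removed edges against sampled non-edges
#'
#' Scores every test pair by the cosine similarity of its endpoint
#' embeddings and computes the exact probability that a removed true
#' edge outranks a sampled non-edge (ties count 1/2), over all
#' `pos x neg` pairs — the Mann-Whitney form of the AUC.
#'
#' @param Y a `node_embedding` or plain `n x d` matrix covering all
#'   endpoints.
#' @param split a `link_split`.
#' @return AUC in `[0, 1]`.
#' @export
auc_ranking <- function(Y, split) {
  Y <- embedding_matrix(Y)
  pos <- cosine_pair_scores(Y, split$pos_edges)
  neg <- cosine_pair_scores(Y, split$neg_edges)
  auc_from_scores(pos, neg)
}

# exact AUC over all pos x neg score pairs; ties count one half
auc_from_scores <- function(pos, neg) {
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# micro/macro F1 over all classes; with `positive` set, also the classic
# binary F1 of that class
f1_scores <- function(truth, pred, positive = NULL) {
  classes <- sort(unique(truth))
  tp <- fp <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp[i] <- sum(pred == cl & truth == cl)
    fp[i] <- sum(pred == cl & truth != cl)
    fn[i] <- sum(pred != cl & truth == cl)
  }
  micro_p <- sum(tp) / max(sum(tp) + sum(fp), 1)
  micro_r <- sum(tp) / max(sum(tp) + sum(fn), 1)
  micro <- if (micro_p + micro_r == 0) 0 else 2 * micro_p * micro_r / (micro_p + micro_r)
  per_class <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  out <- list(micro = micro, macro = mean(per_class))
  if (!is.null(positive)) out$positive_f1 <- per_class[match(positive, classes)]
  out
}

#' Repeated-split node classification on embeddings
#'
#' The standard downstream protocol: per repeat, a random `train_frac`
#' of the labeled nodes trains a linear max-margin classifier
#' (`e1071::svm`, linear kernel, cost 1) on their embeddings; the rest
#' are predicted, and Micro-F1 / Macro-F1 are averaged over repeats. A
#' split is redrawn if some class has no training instance. Embedding
#' columns are standardized once (constant columns left alone) before
#' fitting, so the margin is insensitive to the absolute scale of the
#' embedding coordinates.
#'
#' @param Y a `node_embedding` or plain embedding matrix.
#' @param labels integer label vector (length n, `NA` = unlabeled).
#' @param train_frac fraction of labeled nodes used for training.
#' @param repeats number of random splits.
#' @param seed integer seed.
#' @return list with `micro_f1` and `macro_f1` (means over repeats) and
#'   the per-repeat values.
#' @export
node_classification_eval <- function(Y, labels, train_frac = 0.3, repeats = 10L,
                                     seed = 1L) {
  Y <- embedding_matrix(Y)
  idx <- which(!is.na(labels))
  if (length(unique(labels[idx])) < 2L) {
    stop("node classification needs at least two classes", call. = FALSE)
  }
  Yl <- Y[idx, , drop = FALSE]
  mu <- colMeans(Yl)
  sdv <- apply(Yl, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Yl <- sweep(sweep(Yl, 2, mu), 2, sdv, "/")
  lab <- factor(labels[idx])
  n_lab <- length(idx)
  n_train <- max(2L, round(train_frac * n_lab))
  with_seed(seed, {
    micro <- macro <- numeric(repeats)
    for (r in seq_len(repeats)) {
      for (try in 1:100) {
        tr <- sample.int(n_lab, n_train)
        if (length(unique(lab[tr])) == nlevels(lab) && length(tr) < n_lab) break
      }
      fit <- e1071::svm(x = Yl[tr, , drop = FALSE], y = lab[tr],
                        kernel = "linear", cost = 1, scale = FALSE)
      pred <- predict(fit, Yl[-tr, , drop = FALSE])
      f1 <- f1_scores(as.character(lab[-tr]), as.character(pred))
      micro[r] <- f1$micro
      macro[r] <- f1$macro
    }
    list(micro_f1 = mean(micro), macro_f1 = mean(macro),
         micro_per_repeat = micro, macro_per_repeat = macro)
  })
}

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI = 2 I(A; B) / (H(A) + H(B))} (arithmetic-mean
#' normalization). Two all-in-one partitions are defined as NMI 1.
#'
#' @param a,b membership vectors over the same node set (integer or
#'   factor; labelings are compared up to renaming).
#' @return value in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different node sets", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (ha + hb == 0) return(1)
  denom <- outer(pi_, pj_)
  nz <- pij > 0
  info <- sum(pij[nz] * log(pij[nz] / denom[nz]))
  max(0, min(1, 2 * info / (ha + hb)))
}
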