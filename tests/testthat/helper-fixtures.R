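# shared helpers for building small text fixtures and brute-force oracles

write_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# brute-force cosine similarity with the zero-row convention
brute_cosine <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(M[i, ]^2)); nj <- sqrt(sum(M[j, ]^2))
      S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(M[i, ] * M[j, ]) / (ni * nj)
    }
  }
  S
}

# brute-force Newman modularity: double loop over ordered node pairs
brute_modularity <- function(graph, memb) {
  A <- as.matrix(graph$A)
  d <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (memb[i] == memb[j]) q <- q + A[i, j] - d[i] * d[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# brute-force ranking AUC over all pos x neg score pairs
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force context-pair enumeration, position by position
brute_context_pairs <- function(walks, b) {
  out <- NULL
  for (w in walks) {
    L <- length(w)
    for (i in seq_len(L)) {
      for (j in seq(-b, b)) {
        if (j != 0 && i + j >= 1 && i + j <= L) {
          out <- rbind(out, c(w[i], w[i + j]))
        }
      }
    }
  }
  out
}

# canonical sort of a pair matrix for set comparison
sort_pairs <- function(P) P[order(P[, 1], P[, 2]), , drop = FALSE]

# a small connected attributed graph with 2 planted groups, used by the
# gradient and descent tests
tiny_attributed_graph <- function() {
  A <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  A[edges] <- 1
  A <- A + t(A)
  X <- rbind(
    c(1, 1, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0),
    c(0, 0, 1, 1), c(0, 0, 1, 0), c(0, 0, 1, 1)
  )
  attributed_graph(A, X = X, labels = c(1, 1, 1, 2, 2, 2))
}

# hand-built single-layer parameter set (bypasses the tower-shape
# restriction of init_params for closed-form checks)
manual_params <- function(W_enc, b_enc, W_dec, b_dec, H) {
  structure(list(
    arr = list(enc_W1 = W_enc, enc_b1 = b_enc, dec_W1 = W_dec, dec_b1 = b_dec, H = H),
    sizes_enc = c(nrow(W_enc), ncol(W_enc)),
    sizes_dec = c(nrow(W_dec), ncol(W_dec)),
    K = 1L
  ), class = "model_params")
}
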