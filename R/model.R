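#' Training configuration for the coupled embedding model
#'
#' @param d embedding dimension (must be smaller than the node count).
#' @param hidden integer vector of encoder hidden-layer widths between
#'   the input and the embedding layer; the decoder mirrors them. Widths
#'   must decrease strictly from the input to `d` (a tower). The default
#'   `NULL` resolves at training time to a single hidden layer at the
#'   geometric mean of the input width and `d` (dropped when the graph
#'   is too small to fit one); large sparse networks typically use
#'   deeper towers such as `c(1000, 500)`.
#' @param variant `"csm"` (community-similarity term with its own
#'   weight) or `"am"` (community indicator appended to the attributes).
#' @param eta,psi,phi nonnegative mixing weights of the reconstructed
#'   adjacency (adjacency, attribute-similarity, community-similarity
#'   terms; `phi` is unused under `"am"`).
#' @param chi reconstruction penalty on nonzero entries, > 1.
#' @param alpha weight of the autoencoder loss in the joint objective.
#'   The reconstruction loss is an unnormalized sum over all n^2
#'   penalty-weighted entries while the skip-gram loss sums over context
#'   pairs, so the two branches only exert comparable pull when `alpha`
#'   is small; the default 0.01 was chosen by grid search over powers of
#'   ten on planted-partition graphs.
#' @param gamma weight of the l2 regularizer on encoder/decoder weights.
#' @param lr Adam learning rate.
#' @param batch_size skip-gram pairs per mini-batch.
#' @param ae_batch_size rows per autoencoder mini-batch.
#' @param epochs training epochs (upper bound; early stopping may end
#'   sooner).
#' @param early_stop_tol relative change of the epoch loss below which
#'   training stops.
#' @param early_stop_window number of epochs over which the relative
#'   change is measured.
#' @param normalize how to scale the reconstructed adjacency into the
#'   (-1, 1) range of the tanh output layer: `"global"` (default)
#'   divides by the largest entry, preserving relative row magnitudes
#'   (and hence degree information); `"row"` divides each row by its own
#'   maximum; `"none"` feeds the raw blend. The penalty support is
#'   always computed on the raw matrix.
#' @param walk a [walk_config()].
#' @param seed master seed; walks, initialization, batching and negative
#'   draws all derive from it.
#' @return a `train_config` list.
#' @export
train_config <- function(d = 128L, hidden = NULL, variant = c("csm", "am"),
                         eta = 1, psi = 1, phi = 1, chi = 10,
                         alpha = 0.01, gamma = 1e-4, lr = 1e-3,
                         batch_size = 1024L, ae_batch_size = 64L,
                         epochs = 50L, early_stop_tol = 1e-5,
                         early_stop_window = 5L,
                         normalize = c("global", "row", "none"),
                         walk = walk_config(), seed = 1L) {
  variant <- match.arg(variant)
  normalize <- match.arg(normalize)
  stopifnot(d >= 1, epochs >= 1, alpha >= 0, gamma >= 0, lr > 0,
            batch_size >= 1, ae_batch_size >= 1, chi > 1)
  if (!is.null(hidden)) hidden <- as.integer(hidden)
  structure(list(d = as.integer(d), hidden = hidden,
                 variant = variant, eta = eta, psi = psi, phi = phi,
                 chi = chi, alpha = alpha, gamma = gamma, lr = lr,
                 batch_size = as.integer(batch_size),
                 ae_batch_size = as.integer(ae_batch_size),
                 epochs = as.integer(epochs),
                 early_stop_tol = early_stop_tol,
                 early_stop_window = as.integer(early_stop_window),
                 normalize = normalize,
                 walk = walk, seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize model parameters
#'
#' Encoder and decoder weights use Glorot-uniform initialization; biases
#' start at zero; the skip-gram context matrix `H` starts at zero, the
#' standard choice for the output side of skip-gram models.
#'
#' @param n_in input width (columns of the reconstructed adjacency).
#' @param hidden encoder hidden widths.
#' @param d embedding dimension.
#' @param n_nodes number of nodes (rows of the context matrix).
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return a `model_params` object: flat named list of arrays in `$arr`
#'   (`enc_W<k>`, `enc_b<k>`, `dec_W<k>`, `dec_b<k>`, `H`) plus the
#'   layer-size bookkeeping.
#' @export
init_params <- function(n_in, hidden, d, n_nodes, seed = NULL) {
  sizes_enc <- c(n_in, hidden, d)
  if (any(diff(sizes_enc) >= 0)) {
    stop("layer sizes must strictly decrease from input to embedding", call. = FALSE)
  }
  sizes_dec <- rev(sizes_enc)
  with_seed(seed, {
    arr <- list()
    glorot <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    for (k in seq_len(length(sizes_enc) - 1L)) {
      arr[[paste0("enc_W", k)]] <- glorot(sizes_enc[k], sizes_enc[k + 1])
      arr[[paste0("enc_b", k)]] <- numeric(sizes_enc[k + 1])
    }
    for (k in seq_len(length(sizes_dec) - 1L)) {
      arr[[paste0("dec_W", k)]] <- glorot(sizes_dec[k], sizes_dec[k + 1])
      arr[[paste0("dec_b", k)]] <- numeric(sizes_dec[k + 1])
    }
    arr[["H"]] <- matrix(0, n_nodes, d)
    structure(list(arr = arr, sizes_enc = sizes_enc, sizes_dec = sizes_dec,
                   K = length(sizes_enc) - 1L),
              class = "model_params")
  })
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# forward pass through a tanh stack; returns list of activations, input first
stack_forward <- function(X, params, prefix) {
  K <- params$K
  acts <- vector("list", K + 1L)
  acts[[1]] <- X
  for (k in seq_len(K)) {
    Z <- add_bias(acts[[k]] %*% params$arr[[paste0(prefix, "_W", k)]],
                  params$arr[[paste0(prefix, "_b", k)]])
    acts[[k + 1]] <- tanh(Z)
  }
  acts
}

# backward pass; dTop = dLoss/d(top activation). Returns named grads and
# dLoss/d(input).
stack_backward <- function(acts, dTop, params, prefix) {
  K <- params$K
  g <- list()
  for (k in rev(seq_len(K))) {
    dZ <- dTop * (1 - acts[[k + 1]]^2)
    g[[paste0(prefix, "_W", k)]] <- crossprod(acts[[k]], dZ)
    g[[paste0(prefix, "_b", k)]] <- colSums(dZ)
    dTop <- dZ %*% t(params$arr[[paste0(prefix, "_W", k)]])
  }
  g$d_input <- dTop
  g
}

#' Encode rows of the reconstructed adjacency
#'
#' Applies the tanh encoder stack
#' \eqn{y^{(k)} = \tanh(y^{(k-1)} W^{(k)} + b^{(k)})} to each input row;
#' the final layer is the node embedding.
#'
#' @param R_rows numeric matrix (or single vector) whose row width
#'   matches the encoder input layer.
#' @param params a `model_params` object.
#' @return matrix of `d`-dimensional codes, one row per input row.
#' @export
encode_rows <- function(R_rows, params) {
  if (is.null(dim(R_rows))) R_rows <- matrix(R_rows, nrow = 1)
  if (ncol(R_rows) != params$sizes_enc[1]) {
    stop("input width does not match the encoder input layer", call. = FALSE)
  }
  acts <- stack_forward(R_rows, params, "enc")
  acts[[params$K + 1L]]
}

#' Decode embedding codes back to reconstructed-adjacency rows
#'
#' Mirrored tanh stack of the encoder; the output layer is also tanh,
#' so reconstructions lie in (-1, 1) elementwise.
#'
#' @param codes numeric matrix (or single vector) of `d`-dimensional
#'   codes.
#' @param params a `model_params` object.
#' @return matrix of reconstructed rows.
#' @export
decode_codes <- function(codes, params) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  if (ncol(codes) != params$sizes_dec[1]) {
    stop("code width does not match the decoder input layer", call. = FALSE)
  }
  acts <- stack_forward(codes, params, "dec")
  acts[[params$K + 1L]]
}

#' Penalty-weighted autoencoder reconstruction loss
#'
#' \deqn{L_{ae} = \sum_i \|(\hat R_i - R_i) \odot b_i\|_2^2}
#' With all penalties equal to 1 this is the plain squared
#' reconstruction error.
#'
#' @param R input rows.
#' @param R_hat reconstructed rows, same shape.
#' @param B penalty matrix, same shape (defaults to all ones).
#' @return nonnegative scalar.
#' @export
autoencoder_loss <- function(R, R_hat, B = NULL) {
  R <- as_dense(R); R_hat <- as_dense(R_hat)
  if (!all(dim(R) == dim(R_hat))) stop("R and R_hat shapes differ", call. = FALSE)
  if (is.null(B)) B <- matrix(1, nrow(R), ncol(R))
  if (!all(dim(R) == dim(B))) stop("penalty matrix shape differs", call. = FALSE)
  sum(((R_hat - R) * B)^2)
}

# numerically stable log(sigmoid(x)) = min(x, 0) - log1p(exp(-|x|))
log_sigmoid <- function(x) pmin(x, 0) - log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Skip-gram negative-sampling loss
#'
#' \deqn{-\sum_{pairs}\Big[\log\sigma(h'_{ctx}\cdot y) +
#'   \sum_{s=1}^{|neg|}\log\sigma(-h'_{s}\cdot y)\Big]}
#' where `y` is the encoder code of the pair's center node and `h'` are
#' rows of the context matrix `H`.
#'
#' @param center_codes matrix of codes, one row per (center, context)
#'   pair.
#' @param pos_contexts integer vector of context node indices, one per
#'   pair.
#' @param neg_draws integer matrix (`pairs x |neg|`) of noise node
#'   indices.
#' @param H context matrix (`n x d`).
#' @return scalar loss.
#' @export
sgns_loss <- function(center_codes, pos_contexts, neg_draws, H) {
  if (is.null(dim(center_codes))) center_codes <- matrix(center_codes, nrow = 1)
  if (is.null(dim(neg_draws))) neg_draws <- matrix(neg_draws, nrow = nrow(center_codes))
  spos <- rowSums(center_codes * H[pos_contexts, , drop = FALSE])
  loss <- -sum(log_sigmoid(spos))
  for (s in seq_len(ncol(neg_draws))) {
    sneg <- rowSums(center_codes * H[neg_draws[, s], , drop = FALSE])
    loss <- loss - sum(log_sigmoid(-sneg))
  }
  loss
}

#' l2 regularizer on encoder and decoder weights
#'
#' \eqn{\frac{1}{2}\sum_k (\|W^{(k)}\|_F^2 + \|\hat W^{(k)}\|_F^2)};
#' biases and the context matrix are excluded.
#'
#' @param params a `model_params` object.
#' @return nonnegative scalar.
#' @export
reg_loss <- function(params) {
  s <- 0
  for (k in seq_len(params$K)) {
    s <- s + sum(params$arr[[paste0("enc_W", k)]]^2) +
      sum(params$arr[[paste0("dec_W", k)]]^2)
  }
  s / 2
}

#' Joint objective
#'
#' \eqn{L = L_{sg} + \alpha L_{ae} + \gamma L_{reg}}.
#'
#' @param sg skip-gram loss component.
#' @param ae autoencoder loss component.
#' @param reg regularizer component.
#' @param alpha,gamma mixing weights.
#' @return scalar.
#' @export
total_loss <- function(sg, ae, reg, alpha = 1, gamma = 1e-4) {
  sg + alpha * ae + gamma * reg
}

# --- gradients ------------------------------------------------------------

# autoencoder branch: loss and gradients for a batch of rows.
# weight multiplies both the loss and all gradients (alpha).
ae_loss_grad <- function(params, R_batch, B_batch, weight = 1) {
  enc <- stack_forward(R_batch, params, "enc")
  codes <- enc[[params$K + 1L]]
  dec <- stack_forward(codes, params, "dec")
  R_hat <- dec[[params$K + 1L]]
  diff <- R_hat - R_batch
  loss <- weight * sum((diff * B_batch)^2)
  dRhat <- weight * 2 * diff * B_batch^2
  gdec <- stack_backward(dec, dRhat, params, "dec")
  genc <- stack_backward(enc, gdec$d_input, params, "enc")
  gdec$d_input <- NULL
  genc$d_input <- NULL
  list(loss = loss, grads = c(genc, gdec))
}

# skip-gram branch: loss and gradients for a batch of pairs. Centers
# repeat within a batch, so the encoder runs once per *unique* center
# row and per-pair gradients are pooled before the backward pass.
sg_loss_grad <- function(params, R, centers, pos_contexts, neg_draws) {
  uc <- unique(centers)
  idx <- match(centers, uc)
  enc <- stack_forward(R[uc, , drop = FALSE], params, "enc")
  Yu <- enc[[params$K + 1L]]
  Y <- Yu[idx, , drop = FALSE]
  H <- params$arr$H
  Hpos <- H[pos_contexts, , drop = FALSE]
  spos <- rowSums(Y * Hpos)
  sp <- sigmoid(spos)
  loss <- -sum(log_sigmoid(spos))
  dY <- -(1 - sp) * Hpos
  npair <- length(centers)
  nneg <- ncol(neg_draws)
  ids <- c(pos_contexts, neg_draws)
  contrib <- matrix(0, npair * (1L + nneg), ncol(Y))
  contrib[seq_len(npair), ] <- -(1 - sp) * Y
  for (s in seq_len(nneg)) {
    neg <- neg_draws[, s]
    Hneg <- H[neg, , drop = FALSE]
    sneg <- rowSums(Y * Hneg)
    sn <- sigmoid(sneg)
    loss <- loss - sum(log_sigmoid(-sneg))
    dY <- dY + sn * Hneg
    contrib[s * npair + seq_len(npair), ] <- sn * Y
  }
  gH <- matrix(0, nrow(H), ncol(H))
  acc <- rowsum(contrib, ids)
  gH[as.integer(rownames(acc)), ] <- acc
  dYu <- rowsum(dY, idx)
  dYu <- dYu[order(as.integer(rownames(dYu))), , drop = FALSE]
  genc <- stack_backward(enc, dYu, params, "enc")
  genc$d_input <- NULL
  genc$H <- gH
  list(loss = loss, grads = genc)
}

# gamma * d(reg)/dW added in place to a gradient list
add_reg_grad <- function(grads, params, gamma, enc = TRUE, dec = TRUE) {
  if (gamma == 0) return(grads)
  for (k in seq_len(params$K)) {
    if (enc) {
      nm <- paste0("enc_W", k)
      g <- if (is.null(grads[[nm]])) 0 else grads[[nm]]
      grads[[nm]] <- g + gamma * params$arr[[nm]]
    }
    if (dec) {
      nm <- paste0("dec_W", k)
      g <- if (is.null(grads[[nm]])) 0 else grads[[nm]]
      grads[[nm]] <- g + gamma * params$arr[[nm]]
    }
  }
  grads
}

adam_state <- function(params) {
  list(m = lapply(params$arr, function(a) a * 0),
       v = lapply(params$arr, function(a) a * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params$arr[[nm]] <- params$arr[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flatten / restore parameters (used by the finite-difference tests)
params_to_vector <- function(params) {
  unlist(params$arr, use.names = FALSE)
}

vector_to_params <- function(vec, params) {
  pos <- 0L
  for (nm in names(params$arr)) {
    len <- length(params$arr[[nm]])
    a <- params$arr[[nm]]
    a[] <- vec[pos + seq_len(len)]
    params$arr[[nm]] <- a
    pos <- pos + len
  }
  params
}

# --- reconstruction input -------------------------------------------------

#' Build the reconstructed adjacency and penalty matrix for a graph
#'
#' Assembles the autoencoder input for either variant: under `"am"` the
#' community indicator is appended to the attributes and a single
#' similarity matrix is blended with the adjacency
#' (\eqn{R = \eta A + \psi W^{(S)}}); under `"csm"` the attribute and
#' community similarities enter as separate terms
#' (\eqn{R = \eta A + \psi X^{(S)} + \phi C^{(S)}}). With
#' `assignment = NULL` the community terms are dropped, and with a
#' structure-only graph the attribute terms are dropped, so the blend
#' degrades gracefully to \eqn{\eta A}.
#'
#' @param graph an `attributed_graph`.
#' @param assignment a `community_assignment` or `NULL`.
#' @param variant `"csm"` or `"am"`.
#' @param eta,psi,phi mixing weights.
#' @param chi penalty weight (> 1).
#' @return list with `R` (dense matrix), `B` (penalty matrix, computed
#'   on the raw blend).
#' @export
build_reconstruction <- function(graph, assignment = NULL,
                                 variant = c("csm", "am"),
                                 eta = 1, psi = 1, phi = 1, chi = 10) {
  variant <- match.arg(variant)
  A <- graph$A
  X <- graph$X
  C <- if (is.null(assignment)) NULL else assignment$C
  if (variant == "am") {
    Wmat <- if (is.null(C)) X else concat_attributes_community(X, C)
    if (is.null(Wmat)) {
      R <- new_reconstructed_adjacency(eta * as_dense(A), eta, psi, NA_real_)
    } else {
      R <- reconstructed_adjacency_am(A, cosine_similarity(Wmat), eta, psi)
    }
  } else {
    X_s <- if (is.null(X)) NULL else cosine_similarity(X)
    if (is.null(C)) {
      R0 <- eta * as_dense(A)
      if (!is.null(X_s)) R0 <- R0 + psi * X_s
      R <- new_reconstructed_adjacency(R0, eta, psi, phi)
    } else {
      R <- reconstructed_adjacency_csm(A, X_s, cosine_similarity(as_dense(C)),
                                       eta, psi, phi)
    }
  }
  list(R = R$R, B = penalty_matrix(R, chi))
}

# --- training -------------------------------------------------------------

#' Train the coupled embedding model
#'
#' Alternating mini-batch optimization of the joint objective: each
#' epoch makes one pass over the shuffled skip-gram pairs and, spread
#' evenly among those batches, one pass over the autoencoder rows. The
#' skip-gram batches update the encoder and the context matrix; the
#' autoencoder batches update the encoder and decoder; both include the
#' weight regularizer. Fresh noise nodes are drawn per batch from the
#' degree^(3/4) distribution. Training stops at `epochs` or earlier when
#' the epoch loss plateaus.
#'
#' @param graph an `attributed_graph`.
#' @param assignment a `community_assignment`, or `NULL` to ignore
#'   community structure.
#' @param config a [train_config()].
#' @param verbose print per-epoch loss components.
#' @return a `node_embedding`: list with `Y` (`n x d` matrix, external
#'   node ids as row names), `d`, `history` (per-epoch loss data frame,
#'   with the pre-training loss as epoch 0) and `params`.
#' @export
train_embedding <- function(graph, assignment = NULL, config = train_config(),
                            verbose = FALSE) {
  n <- graph$n
  if (config$d >= n) stop("embedding dimension must be smaller than the node count", call. = FALSE)
  if (is.null(config$hidden)) {
    mid <- as.integer(round(sqrt(as.numeric(n) * config$d)))
    config$hidden <- if (mid > config$d && mid < n) mid else integer(0)
  }
  rec <- build_reconstruction(graph, assignment, config$variant,
                              config$eta, config$psi, config$phi, config$chi)
  R <- rec$R
  B <- rec$B
  if (config$normalize == "global") {
    rmax <- max(abs(R))
    if (rmax > 0) R <- R / rmax
  } else if (config$normalize == "row") {
    rmax <- apply(abs(R), 1, max)
    R <- R * ifelse(rmax > 0, 1 / rmax, 1)
  }
  degs <- degrees(graph)
  noise_tab <- negative_sampler_table(degs)
  nneg <- config$walk$num_negatives

  with_seed(config$seed, {
    walks <- generate_walks(graph, config$walk,
                            seed = sample.int(.Machine$integer.max, 1L))
    pairs <- context_pairs(walks, config$walk$window)
    if (nrow(pairs) == 0L) stop("walk corpus produced no context pairs", call. = FALSE)
    params <- init_params(n, config$hidden, config$d, n, seed = NULL)
    state <- adam_state(params)

    n_pairs <- nrow(pairs)
    n_sg <- max(1L, ceiling(n_pairs / config$batch_size))
    ae_batches <- split(seq_len(n), ceiling(seq_len(n) / config$ae_batch_size))
    n_ae <- length(ae_batches)
    ae_after <- round(seq(1, n_sg, length.out = n_ae))

    history <- data.frame(epoch = integer(0), sg = numeric(0), ae = numeric(0),
                          reg = numeric(0), total = numeric(0))
    # pre-training loss on a fixed evaluation noise draw
    eval_negs <- matrix(alias_draw(noise_tab, n_pairs * nneg), n_pairs, nneg)
    full_loss <- function(par) {
      sg <- 0
      Yall <- encode_rows(R, par)
      chunk <- 200000L
      for (lo in seq(1L, n_pairs, by = chunk)) {
        hi <- min(lo + chunk - 1L, n_pairs)
        sg <- sg + sgns_loss(Yall[pairs[lo:hi, 1], , drop = FALSE],
                             pairs[lo:hi, 2],
                             eval_negs[lo:hi, , drop = FALSE], par$arr$H)
      }
      ae <- autoencoder_loss(R, decode_codes(encode_rows(R, par), par), B)
      rg <- reg_loss(par)
      c(sg = sg, ae = ae, reg = rg,
        total = total_loss(sg, ae, rg, config$alpha, config$gamma))
    }
    l0 <- full_loss(params)
    history[1, ] <- c(0, l0)
    if (verbose) message(sprintf("epoch 0: total %.4f", l0[["total"]]))

    epoch_tot <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_pairs)
      ae_order <- sample(ae_batches)
      ae_ptr <- 1L
      sg_sum <- 0; ae_sum <- 0
      for (bi in seq_len(n_sg)) {
        lo <- (bi - 1L) * config$batch_size + 1L
        hi <- min(bi * config$batch_size, n_pairs)
        sel <- ord[lo:hi]
        negs <- matrix(alias_draw(noise_tab, length(sel) * nneg),
                       length(sel), nneg)
        sg <- sg_loss_grad(params, R, pairs[sel, 1], pairs[sel, 2], negs)
        g <- add_reg_grad(sg$grads, params, config$gamma, dec = FALSE)
        upd <- adam_step(params, g, state, config$lr)
        params <- upd$params; state <- upd$state
        sg_sum <- sg_sum + sg$loss
        while (ae_ptr <= length(ae_after) && ae_after[ae_ptr] == bi) {
          rows <- ae_order[[ae_ptr]]
          ae <- ae_loss_grad(params, R[rows, , drop = FALSE],
                             B[rows, , drop = FALSE], weight = config$alpha)
          g <- add_reg_grad(ae$grads, params, config$gamma)
          upd <- adam_step(params, g, state, config$lr)
          params <- upd$params; state <- upd$state
          ae_sum <- ae_sum + ae$loss
          ae_ptr <- ae_ptr + 1L
        }
      }
      rg <- reg_loss(params)
      tot <- sg_sum + ae_sum + config$gamma * rg
      if (!is.finite(tot)) {
        stop(sprintf("non-finite loss at epoch %d (sg %.3g, ae %.3g, reg %.3g)",
                     epoch, sg_sum, ae_sum, rg), call. = FALSE)
      }
      history[nrow(history) + 1L, ] <-
        c(epoch, sg_sum, ae_sum / max(config$alpha, 1e-300), rg, tot)
      epoch_tot[epoch] <- tot
      if (verbose) message(sprintf("epoch %d: total %.4f", epoch, tot))
      w <- config$early_stop_window
      if (epoch > w) {
        rel <- abs(epoch_tot[epoch] - epoch_tot[epoch - w]) /
          max(abs(epoch_tot[epoch]), 1e-12)
        if (rel < config$early_stop_tol) break
      }
    }
    lf <- full_loss(params)
    Y <- encode_rows(R, params)
    rownames(Y) <- graph$node_ids
    structure(list(Y = Y, d = config$d, history = history,
                   initial_loss = l0, final_loss = lf,
                   params = params, config = config),
              class = "node_embedding")
  })
}

#' @export
print.node_embedding <- function(x, ...) {
  cat(sprintf("node_embedding: %d nodes, d = %d (%s variant, %d epochs run)\n",
              nrow(x$Y), x$d, x$config$variant, max(x$history$epoch)))
  invisible(x)
}
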