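#' Pairwise cosine similarity of matrix rows
#'
#' \eqn{s_{ij} = M_i \cdot M_j / (\|M_i\|\,\|M_j\|)}. Rows that are all
#' zero have no direction, so their similarity to every row (themselves
#' included) is defined as 0: a node without attributes should not be
#' declared similar to anyone.
#'
#' @param M numeric matrix (rows = nodes). Dense or sparse.
#' @param top_k optional integer: keep only the `top_k` largest
#'   off-diagonal similarities per row (zeroing the rest, symmetrically:
#'   an entry survives if it is in the top-k of either endpoint). `NULL`
#'   (default) keeps the dense matrix; thresholding is a memory valve
#'   for large graphs, not part of the model definition.
#' @return symmetric dense `n x n` similarity matrix; entries lie in
#'   `[0, 1]` for nonnegative input.
#' @export
cosine_similarity <- function(M, top_k = NULL) {
  M <- as_dense(M)
  nrm <- sqrt(rowSums(M^2))
  S <- tcrossprod(M)
  inv <- ifelse(nrm > 0, 1 / nrm, 0)
  S <- S * outer(inv, inv)
  # exact 1 on the diagonal of nonzero rows, exact 0 on zero rows
  diag(S) <- as.numeric(nrm > 0)
  if (!is.null(top_k)) {
    n <- nrow(S)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      off <- S[i, ]; off[i] <- -Inf
      k <- min(top_k, n - 1L)
      if (k > 0) keep[i, order(off, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
    keep <- keep | t(keep)
    diag(keep) <- TRUE
    S[!keep] <- 0
  }
  S
}

#' Concatenate attributes with the community indicator matrix
#'
#' Builds the augmented attribute matrix `W = [X | C]` used by the
#' variant that treats community membership as extra node attributes.
#' In structure-only mode (`X = NULL`) the result is the community
#' indicator alone.
#'
#' @param X node attribute matrix (`n x f`) or `NULL`.
#' @param C community one-hot indicator (`n x l`), e.g.
#'   `assignment$C`.
#' @return dense `n x (f + l)` matrix.
#' @export
concat_attributes_community <- function(X, C) {
  C <- as_dense(C)
  if (is.null(X)) {
    if (ncol(C) == 0L) stop("nothing to merge: no attributes and no communities", call. = FALSE)
    return(C)
  }
  X <- as_dense(X)
  if (nrow(X) != nrow(C)) stop("attribute and community row counts differ", call. = FALSE)
  if (ncol(X) == 0L && ncol(C) == 0L) stop("nothing to merge: no attributes and no communities", call. = FALSE)
  cbind(X, C)
}

new_reconstructed_adjacency <- function(R, eta, psi, phi) {
  structure(list(R = R, eta = eta, psi = psi, phi = phi),
            class = "reconstructed_adjacency")
}

check_mix_weight <- function(w, name) {
  stop_if_not_scalar_number(w, name)
  if (w < 0) stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
}

#' Reconstructed adjacency, attribute-merge variant
#'
#' \deqn{R = \eta A + \psi W^{(S)}}
#' where `W_s` is the cosine similarity of the augmented attribute
#' matrix `[X | C]`. The blend densifies the sparse adjacency with
#' attribute/community evidence of shared neighborhoods before it is
#' fed to the autoencoder.
#'
#' @param A adjacency matrix (`n x n`).
#' @param W_s similarity matrix of the augmented attributes (`n x n`).
#' @param eta,psi nonnegative mixing weights for `A` and `W_s`.
#' @return a `reconstructed_adjacency` (list with dense matrix `R` and
#'   the weights used).
#' @export
reconstructed_adjacency_am <- function(A, W_s, eta = 1, psi = 1) {
  check_mix_weight(eta, "eta"); check_mix_weight(psi, "psi")
  A <- as_dense(A); W_s <- as_dense(W_s)
  if (!all(dim(A) == dim(W_s))) stop("A and W_s must have the same shape", call. = FALSE)
  new_reconstructed_adjacency(eta * A + psi * W_s, eta, psi, NA_real_)
}

#' Reconstructed adjacency, community-similarity variant
#'
#' \deqn{R = \eta A + \psi X^{(S)} + \phi C^{(S)}}
#' with separate weights for the attribute similarity `X_s` and the
#' community similarity `C_s`, so the two information channels can be
#' balanced independently. In structure-only mode pass `X_s = NULL` and
#' the attribute term is dropped.
#'
#' @param A adjacency matrix (`n x n`).
#' @param X_s attribute cosine-similarity matrix or `NULL`.
#' @param C_s community cosine-similarity matrix (`n x n`).
#' @param eta,psi,phi nonnegative mixing weights.
#' @return a `reconstructed_adjacency`.
#' @export
reconstructed_adjacency_csm <- function(A, X_s, C_s, eta = 1, psi = 1, phi = 1) {
  check_mix_weight(eta, "eta"); check_mix_weight(psi, "psi"); check_mix_weight(phi, "phi")
  A <- as_dense(A); C_s <- as_dense(C_s)
  if (!all(dim(A) == dim(C_s))) stop("A and C_s must have the same shape", call. = FALSE)
  R <- eta * A + phi * C_s
  if (!is.null(X_s)) {
    X_s <- as_dense(X_s)
    if (!all(dim(A) == dim(X_s))) stop("A and X_s must have the same shape", call. = FALSE)
    R <- R + psi * X_s
  }
  new_reconstructed_adjacency(R, eta, psi, phi)
}

#' Reconstruction penalty matrix
#'
#' Entries of the reconstructed adjacency that are nonzero carry the
#' informative edge/similarity signal, so their reconstruction errors
#' are up-weighted: \eqn{b_{ij} = \chi > 1} where \eqn{r_{ij} \neq 0}
#' and 1 elsewhere. A numerical zero test `|r_ij| > 1e-12` guards
#' against float fuzz in the blended similarities.
#'
#' @param R a `reconstructed_adjacency` or a plain matrix.
#' @param chi penalty weight, strictly greater than 1.
#' @return dense `n x n` matrix with entries in `{1, chi}`.
#' @export
penalty_matrix <- function(R, chi = 10) {
  stop_if_not_scalar_number(chi, "chi")
  if (chi <= 1) stop("`chi` must be > 1", call. = FALSE)
  M <- if (inherits(R, "reconstructed_adjacency")) R$R else as_dense(R)
  B <- matrix(1, nrow(M), ncol(M))
  B[abs(M) > 1e-12] <- chi
  B
}
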