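#' Construct an attributed graph
#'
#' The central container of the package: a simple undirected, unweighted
#' graph together with optional nonnegative node attributes and optional
#' node labels. External node identifiers (arbitrary tokens) are mapped
#' to dense internal indices `1..n`; all matrices are ordered by that
#' internal index.
#'
#' @param A symmetric binary adjacency matrix (dense or `Matrix` sparse),
#'   zero diagonal.
#' @param node_ids character vector of external identifiers, one per node.
#'   Defaults to `"0" .. "n-1"`.
#' @param X optional nonnegative attribute matrix with one row per node,
#'   or `NULL` for structure-only graphs (e.g. connectomes without
#'   per-node annotation).
#' @param labels optional integer vector of class labels, one per node,
#'   `NA` for unlabeled nodes.
#' @return an object of class `attributed_graph`: a list with elements
#'   `n`, `node_ids`, `A` (sparse `dgCMatrix`), `X`, `labels`.
#' @export
attributed_graph <- function(A, node_ids = NULL, X = NULL, labels = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency matrix must be square", call. = FALSE)
  if (!Matrix::isSymmetric(A)) stop("adjacency matrix must be symmetric", call. = FALSE)
  if (any(Matrix::diag(A) != 0)) stop("adjacency matrix must have zero diagonal", call. = FALSE)
  vals <- A@x
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1 (unweighted graph)", call. = FALSE)
  }
  A <- Matrix::drop0(A)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n) - 1L)
  if (length(node_ids) != n) stop("`node_ids` length must equal node count", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("`node_ids` must be unique", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("attribute matrix must have one row per node", call. = FALSE)
    if (any(X < 0)) stop("attribute matrix must be nonnegative", call. = FALSE)
    storage.mode(X) <- "double"
  }
  if (!is.null(labels)) {
    if (length(labels) != n) stop("`labels` length must equal node count", call. = FALSE)
    labels <- as.integer(labels)
  }
  structure(
    list(n = n, node_ids = as.character(node_ids), A = A, X = X, labels = labels),
    class = "attributed_graph"
  )
}

#' @export
print.attributed_graph <- function(x, ...) {
  m <- Matrix::nnzero(x$A) / 2
  cat(sprintf(
    "attributed_graph: %d nodes, %d edges, %s attributes, %s labels\n",
    x$n, m,
    if (is.null(x$X)) "no" else sprintf("%d", ncol(x$X)),
    if (is.null(x$labels)) "no" else sprintf("%d labeled", sum(!is.na(x$labels)))
  ))
  invisible(x)
}

#' Number of edges of an attributed graph
#' @param graph an `attributed_graph`.
#' @return integer edge count.
#' @export
edge_count <- function(graph) {
  as.integer(Matrix::nnzero(graph$A) / 2)
}

#' Degrees of an attributed graph
#' @param graph an `attributed_graph`.
#' @return integer vector of node degrees.
#' @export
degrees <- function(graph) {
  as.integer(Matrix::rowSums(graph$A))
}

#' Convert to an igraph object
#'
#' Used internally for connectivity checks; exported because it is the
#' natural bridge to the wider R graph ecosystem.
#'
#' @param graph an `attributed_graph`.
#' @return an `igraph` undirected graph whose vertex order matches the
#'   internal node order.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$A, mode = "undirected")
}

# internal: m x 2 matrix of edges (i < j), internal indices
edge_matrix <- function(graph) {
  Atri <- Matrix::triu(graph$A)
  idx <- Matrix::which(Atri != 0, arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2, dimnames = NULL)
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

#' Read an undirected edge list
#'
#' Parses a whitespace-separated two-column edge list into an
#' [attributed_graph()]. Lines starting with `#` and blank lines are
#' ignored; duplicate edges and self-loops are dropped with a message
#' reporting the counts. Node order is first appearance in the file.
#'
#' @param path path to the edge-list file.
#' @return an `attributed_graph` without attributes or labels.
#' @export
read_edge_list <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop(sprintf("empty edge list: %s", path), call. = FALSE)
  toks <- strsplit(trimws(dat$lines), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop(sprintf(
      "malformed edge list line %d in %s: need at least 2 tokens",
      dat$lineno[bad[1]], path
    ), call. = FALSE)
  }
  from <- vapply(toks, `[`, character(1), 1L)
  to <- vapply(toks, `[`, character(1), 2L)
  ids <- unique(as.vector(rbind(from, to)))  # first-appearance order
  i <- match(from, ids)
  j <- match(to, ids)
  n_self <- sum(i == j)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * length(ids) + hi
  n_dup <- sum(duplicated(key))
  uniq <- !duplicated(key)
  lo <- lo[uniq]; hi <- hi[uniq]
  if (n_self + n_dup > 0) {
    message(sprintf(
      "read_edge_list: dropped %d duplicate edge(s) and %d self-loop(s)",
      n_dup, n_self
    ))
  }
  n <- length(ids)
  A <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(n, n)
  )
  attributed_graph(A, node_ids = ids)
}

#' Read a node attribute matrix
#'
#' Reads nonnegative node attributes either as sparse triplets
#' (`node attr value`, 0-based attribute indices) or as dense rows keyed
#' by node id (`node v1 v2 ... vf`). An empty file signals structure-only
#' mode and returns `NULL`.
#'
#' @param path path to the attribute file.
#' @param graph the `attributed_graph` the attributes belong to (supplies
#'   the node-id mapping and node count).
#' @param format `"auto"`, `"triplet"` or `"dense"`. Under `"auto"`, files
#'   whose lines all carry exactly three tokens with an integer second
#'   token are parsed as triplets.
#' @return an `n x f` nonnegative numeric matrix, or `NULL` for an empty
#'   file.
#' @export
read_attribute_matrix <- function(path, graph, format = c("auto", "triplet", "dense")) {
  format <- match.arg(format)
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) return(NULL)
  toks <- strsplit(trimws(dat$lines), "\\s+")
  if (format == "auto") {
    second <- vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, character(1))
    is_trip <- all(lengths(toks) == 3L) &&
      all(grepl("^[0-9]+$", second))
    format <- if (is_trip) "triplet" else "dense"
  }
  node_tok <- vapply(toks, `[`, character(1), 1L)
  row <- match(node_tok, graph$node_ids)
  if (anyNA(row)) {
    stop(sprintf(
      "attribute file line %d: node '%s' is not in the graph",
      dat$lineno[which(is.na(row))[1]], node_tok[which(is.na(row))[1]]
    ), call. = FALSE)
  }
  if (format == "triplet") {
    if (any(lengths(toks) != 3L)) stop("triplet attribute lines need exactly 3 tokens", call. = FALSE)
    attr_idx <- as.integer(vapply(toks, `[`, character(1), 2L)) + 1L
    val <- as.numeric(vapply(toks, `[`, character(1), 3L))
    if (anyNA(val)) stop("non-numeric attribute value", call. = FALSE)
    if (any(val < 0)) stop("negative attribute value", call. = FALSE)
    f <- max(attr_idx)
    X <- matrix(0, graph$n, f)
    X[cbind(row, attr_idx)] <- val
  } else {
    width <- unique(lengths(toks)) - 1L
    if (length(width) != 1L || width < 1L) {
      stop("dense attribute rows must all have the same number of values", call. = FALSE)
    }
    vals <- vapply(toks, function(t) as.numeric(t[-1]), numeric(width))
    vals <- if (width == 1L) matrix(vals, nrow = 1) else vals
    if (anyNA(vals)) stop("non-numeric attribute value", call. = FALSE)
    if (any(vals < 0)) stop("negative attribute value", call. = FALSE)
    X <- matrix(0, graph$n, width)
    X[row, ] <- t(vals)
  }
  X
}

#' Read node labels
#'
#' Two-column `node label` file; labels are arbitrary tokens compacted to
#' integer ids `1..k` in first-appearance order. Nodes absent from the
#' file are `NA` (unlabeled).
#'
#' @param path path to the label file.
#' @param graph the `attributed_graph` the labels belong to.
#' @return integer label vector of length `n` with `NA` for unlabeled
#'   nodes.
#' @export
read_labels <- function(path, graph) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop(sprintf("empty label file: %s", path), call. = FALSE)
  toks <- strsplit(trimws(dat$lines), "\\s+")
  if (any(lengths(toks) < 2L)) {
    stop(sprintf(
      "malformed label line %d: need 'node label'",
      dat$lineno[which(lengths(toks) < 2L)[1]]
    ), call. = FALSE)
  }
  node_tok <- vapply(toks, `[`, character(1), 1L)
  lab_tok <- vapply(toks, `[`, character(1), 2L)
  row <- match(node_tok, graph$node_ids)
  if (anyNA(row)) {
    stop(sprintf("label file: node '%s' is not in the graph",
                 node_tok[which(is.na(row))[1]]), call. = FALSE)
  }
  labels <- rep(NA_integer_, graph$n)
  labels[row] <- match(lab_tok, unique(lab_tok))
  labels
}

#' Write node embeddings to a word2vec-style text file
#'
#' Header line `n d`, then one line per node: the external node id
#' followed by `d` coordinates. Reading the file back with
#' [read_embedding()] reproduces the matrix to printed precision.
#'
#' @param Y numeric `n x d` embedding matrix with finite entries,
#'   `d >= 1`.
#' @param path output path.
#' @param node_ids external identifiers to write, one per row; defaults
#'   to the row names of `Y` or `0..n-1`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(Y, path, node_ids = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 1L) stop("embedding must have at least one dimension", call. = FALSE)
  if (!all(is.finite(Y))) stop("embedding contains non-finite entries", call. = FALSE)
  if (is.null(node_ids)) {
    node_ids <- rownames(Y)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(Y)) - 1L)
  }
  if (length(node_ids) != nrow(Y)) stop("`node_ids` length must match rows of Y", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(Y), ncol(Y)), con)
  body <- apply(Y, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(paste(node_ids, body), con)
  invisible(path)
}

#' Read embeddings written by [write_embedding()]
#'
#' @param path path to the embedding file.
#' @return numeric matrix with external node ids as row names.
#' @export
read_embedding <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop(sprintf("empty embedding file: %s", path), call. = FALSE)
  hdr <- as.integer(strsplit(trimws(dat$lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad embedding header: expected 'n d'", call. = FALSE)
  body <- strsplit(trimws(dat$lines[-1]), "\\s+")
  if (length(body) != hdr[1]) stop("embedding row count does not match header", call. = FALSE)
  ids <- vapply(body, `[`, character(1), 1L)
  Y <- t(vapply(body, function(t) as.numeric(t[-1]), numeric(hdr[2])))
  rownames(Y) <- ids
  Y
}
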