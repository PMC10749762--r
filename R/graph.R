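#' Pairwise Euclidean distances between sample latent features
#'
#' @param latent Numeric matrix, one row per sample (>= 2 rows, no NAs).
#' @return A symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(latent) {
  x <- as.matrix(latent)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x)) stop("NaN/NA in latent features")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- NULL
  diag(d) <- 0
  d
}

#' Build the kNN inter-host similarity graph from a distance matrix
#'
#' Each sample is connected to its `k` closest other samples; the directed
#' relation is symmetrized by union (an undirected edge exists if either
#' endpoint selects the other), since the graph convolution assumes a
#' symmetric adjacency. Ties at the k-th distance are broken by node index
#' (lower index wins) so construction is deterministic. Self-loops are then
#' added and the symmetric-normalized convolution operator
#' \eqn{\tilde{D}^{-1/2}(A + I)\tilde{D}^{-1/2}} is precomputed.
#'
#' @param distances Symmetric n x n distance matrix.
#' @param k Number of nearest neighbours, `0 < k < n` (default 5).
#' @param node_order Optional sample IDs in matrix order.
#' @return A `similarity_graph` with fields `n`, `adjacency`,
#'   `adjacency_with_self`, `norm_operator`, `node_order`, `k`.
#' @export
knn_edges <- function(distances, k = 5L, node_order = NULL) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k (", k, ") must be smaller than the number of nodes (", n, ")")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # order by distance, ties by node index
    nb <- others[order(d[i, others], others)][seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                       # union symmetrization
  diag(A) <- 0
  At <- A + diag(n)
  dtil <- rowSums(At)
  inv_sqrt <- 1 / sqrt(dtil)
  S <- At * tcrossprod(inv_sqrt)
  structure(list(n = n, adjacency = A, adjacency_with_self = At,
                 norm_operator = S,
                 node_order = node_order %||% as.character(seq_len(n)),
                 k = as.integer(k)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph: ", x$n, " nodes, ",
      sum(x$adjacency) / 2, " undirected edges (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Build the similarity graph over concatenated train and test samples
#'
#' Train nodes come first, then test nodes, each preserving input order.
#'
#' @param train_latent,test_latent Latent feature matrices with equal width.
#' @param k Neighbours per node.
#' @param train_ids,test_ids Optional node identifiers.
#' @return A `similarity_graph` over `nrow(train) + nrow(test)` nodes.
#' @export
build_graph <- function(train_latent, test_latent, k = 5L,
                        train_ids = NULL, test_ids = NULL) {
  a <- as.matrix(train_latent); b <- as.matrix(test_latent)
  if (ncol(a) != ncol(b)) stop("latent dimensions differ")
  ids <- c(train_ids %||% paste0("train", seq_len(nrow(a))),
           test_ids %||% paste0("test", seq_len(nrow(b))))
  knn_edges(pairwise_euclidean(rbind(a, b)), k = k, node_order = ids)
}

#' Export graph edges as a TSV edge list
#'
#' @param graph A `similarity_graph`.
#' @param path Output path; columns node_id_1, node_id_2 (undirected, each
#'   edge once with the lower index first).
#' @export
write_edges <- function(graph, path) {
  e <- which(upper.tri(graph$adjacency) & graph$adjacency > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(node_id_1 = graph$node_order[e[, 1L]],
               node_id_2 = graph$node_order[e[, 2L]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
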