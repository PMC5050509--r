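# The weighted sample graph (WSG): nodes are samples, edges join union
# k-nearest-neighbour pairs in the current gene subspace, and each edge
# carries weight exp(-d) with d the Euclidean distance in that subspace.
# Squared distances are maintained incrementally because adding a gene g
# adds exactly (x_ig - x_jg)^2 to every pair, which is what makes the
# forward search's O(lambda * n * m^2) sweep affordable.

#' Pairwise squared Euclidean distances in a gene subset
#'
#' @param x Expression matrix (samples x genes).
#' @param subset Gene indices or identifiers; must be non-empty and
#'   duplicate-free.
#' @return A `distance_state`: symmetric matrix of squared distances with a
#'   zero diagonal and the subset recorded in its `"subset"` attribute.
#' @export
squared_distances <- function(x, subset) {
  idx <- gene_indices(x, subset)
  if (length(idx) == 0L) stop("gene subset must be non-empty", call. = FALSE)
  if (anyDuplicated(idx)) stop("duplicate genes in subset", call. = FALSE)
  sub <- unclass_matrix(x)[, idx, drop = FALSE]
  cp <- tcrossprod(sub)
  sq <- diag(cp)
  D <- outer(sq, sq, "+") - 2 * cp
  D <- (D + t(D)) / 2           # exact symmetry despite rounding
  D[D < 0] <- 0
  diag(D) <- 0
  structure(D, subset = idx, class = "distance_state")
}

#' Extend a distance state by one gene
#'
#' Adds `(x_ig - x_jg)^2` to every pair, giving exactly
#' `squared_distances(x, c(subset, gene))` without touching the genes
#' already accumulated. The input state is left unchanged.
#'
#' @param state A `distance_state` from [squared_distances()].
#' @param x The expression matrix the state was built from.
#' @param gene A single gene index or identifier not already in the state.
#' @return A new `distance_state` on the enlarged subset.
#' @export
extend_distances <- function(state, x, gene) {
  g <- gene_indices(x, gene)
  if (length(g) != 1L) stop("extend one gene at a time", call. = FALSE)
  subset <- attr(state, "subset")
  if (g %in% subset)
    stop("gene ", g, " already in subset", call. = FALSE)
  v <- unclass_matrix(x)[, g]
  D <- unclass(state) + outer(v, v, "-")^2
  diag(D) <- 0
  structure(D, subset = c(subset, g), class = "distance_state")
}

#' k-nearest-neighbour sets from a distance state
#'
#' Each sample's set holds its `k` nearest other samples by squared
#' distance, self excluded, ties broken by ascending sample index. `k` at
#' or above the sample count is clamped to `m - 1` with a warning.
#'
#' @param state A `distance_state` (or any symmetric distance matrix).
#' @param k Number of neighbours, at least 1.
#' @return List of integer vectors, one per sample.
#' @export
knn_sets <- function(state, k) {
  D <- unclass(state)
  m <- nrow(D)
  k <- clamp_k(k, m)
  diag(D) <- Inf
  lapply(seq_len(m), function(i) order(D[i, ])[seq_len(k)])
}

clamp_k <- function(k, m) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k >= m) {
    warning(sprintf("k = %d clamped to m - 1 = %d", k, m - 1L), call. = FALSE)
    k <- m - 1L
  }
  as.integer(k)
}

# Directed-kNN logical mask (row i TRUE at its k nearest columns), then the
# union rule symmetrizes it. Kept separate from knn_sets so the selector's
# hot loop can skip the list allocation.
knn_mask <- function(D, k) {
  m <- nrow(D)
  diag(D) <- Inf
  mask <- matrix(FALSE, m, m)
  for (i in seq_len(m)) mask[i, order(D[i, ])[seq_len(k)]] <- TRUE
  mask | t(mask)
}

#' Build the weighted sample graph on a gene subset
#'
#' There is an (undirected) edge between samples i and j whenever i is
#' among j's k nearest neighbours or vice versa; its weight is
#' `exp(-d(i, j))` with `d` the Euclidean distance in the subset's gene
#' space. No self-loops.
#'
#' @param x Expression matrix (samples x genes).
#' @param subset Gene indices or identifiers.
#' @param k Number of neighbours (clamped to `m - 1` as in [knn_sets()]).
#' @return An object of class `"wsg"`: list with the affinity matrix `A`,
#'   `k`, and the resolved gene `subset`.
#' @export
build_wsg <- function(x, subset, k) {
  D <- squared_distances(x, subset)
  wsg_from_distances(D, k)
}

#' Weighted sample graph from a precomputed distance state
#'
#' @param state A `distance_state`.
#' @param k Number of neighbours.
#' @return A `"wsg"` object as in [build_wsg()].
#' @export
wsg_from_distances <- function(state, k) {
  D <- unclass(state)
  k <- clamp_k(k, nrow(D))
  mask <- knn_mask(D, k)
  A <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  A[mask] <- exp(-sqrt(D[mask]))
  diag(A) <- 0
  structure(list(A = A, k = k, subset = attr(state, "subset")),
            class = "wsg")
}

#' @export
print.wsg <- function(x, ...) {
  ne <- sum(x$A > 0) / 2
  cat(sprintf("weighted sample graph: %d samples, %d edges, k = %d, |subset| = %d\n",
              nrow(x$A), ne, x$k, length(x$subset)))
  invisible(x)
}

#' Export a weighted sample graph as an undirected edge list
#'
#' @param graph A `"wsg"` object.
#' @param path Optional TSV path; when given, a three-column table
#'   (i, j, weight) is written.
#' @return Data frame with columns `i`, `j`, `weight` (i < j), invisibly
#'   when `path` is given.
#' @export
wsg_edges <- function(graph, path = NULL) {
  A <- graph$A
  ut <- upper.tri(A) & A > 0
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = A[ut])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
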