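# The local-modularity score family. Communities are always the given
# class labels, never inferred. Three scores:
#   LM    = sum_k [ m_k/M_k - (d_k/(2 M_k))^2 ]    (unweighted)
#   WLM   = sum_k [ w_k/W_k - (s_k/(2 W_k))^2 ]    (weighted)
#   WLM^s = sum_k   w_k/(w_k + w_k_out)            (simplified; the selector's
#                                                   objective)
# where per class k: w_k is the internal edge weight, w_k_out the boundary
# edge weight (counted once per adjacent class, so s_k = 2 w_k + w_k_out),
# W_k = w_k + w_k_out, s_k the summed node strength; m_k, M_k, d_k are the
# unweighted analogues. A class with an empty denominator contributes 0 so
# that degenerate folds with singleton classes never crash a run.

#' Per-class community weight aggregates of a labelled sample graph
#'
#' @param graph A `"wsg"` object or a symmetric non-negative affinity
#'   matrix with zero diagonal.
#' @param labels Per-node class labels (any vector or factor, one per node).
#' @return Data frame, one row per class, with columns `class`, `n_samples`,
#'   `w` (internal weight), `w_out` (boundary weight), `W` (= w + w_out),
#'   `s` (summed strength), and the unweighted analogues `m_edges`
#'   (internal edges), `b_edges` (boundary edges), `M` (= m_edges +
#'   b_edges), `d` (summed degree).
#' @export
community_weights <- function(graph, labels) {
  A <- graph_affinity(graph)
  m <- nrow(A)
  if (length(labels) != m)
    stop(sprintf("%d labels for %d graph nodes", length(labels), m),
         call. = FALSE)
  labels <- factor(as.vector(labels))
  B <- (A > 0) + 0
  rows <- lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    s <- sum(A[idx, , drop = FALSE])
    w <- sum(A[idx, idx, drop = FALSE]) / 2
    d <- sum(B[idx, , drop = FALSE])
    me <- sum(B[idx, idx, drop = FALSE]) / 2
    data.frame(class = cl, n_samples = length(idx),
               w = w, w_out = s - 2 * w, W = s - w, s = s,
               m_edges = me, b_edges = d - 2 * me, M = d - me, d = d)
  })
  do.call(rbind, rows)
}

graph_affinity <- function(graph) {
  A <- if (inherits(graph, "wsg")) graph$A else unclass(graph)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("graph must be a wsg or a square affinity matrix", call. = FALSE)
  if (any(A < 0)) stop("affinity weights must be non-negative", call. = FALSE)
  A
}

score_result <- function(terms, cw) {
  structure(list(value = sum(terms),
                 terms = stats::setNames(terms, cw$class),
                 weights = cw),
            class = "modularity_score")
}

#' @export
print.modularity_score <- function(x, ...) {
  cat(sprintf("modularity score: %.6f\n", x$value))
  print(round(x$terms, 6))
  invisible(x)
}

#' Local modularity (unweighted)
#'
#' Treats every positive affinity as an edge and scores each class by its
#' internal edge density against its boundary, penalized by squared
#' relative degree: `sum_k [ m_k/M_k - (d_k/(2 M_k))^2 ]`.
#'
#' @inheritParams community_weights
#' @return A `"modularity_score"`: list with the total `value`, per-class
#'   `terms`, and the [community_weights()] table.
#' @export
local_modularity <- function(graph, labels) {
  cw <- community_weights(graph, labels)
  terms <- ifelse(cw$M > 0, cw$m_edges / cw$M - (cw$d / (2 * cw$M))^2, 0)
  score_result(terms, cw)
}

#' Weight local modularity
#'
#' The weighted analogue of [local_modularity()]:
#' `sum_k [ w_k/W_k - (s_k/(2 W_k))^2 ]`.
#'
#' @inheritParams community_weights
#' @return A `"modularity_score"`.
#' @export
weight_local_modularity <- function(graph, labels) {
  cw <- community_weights(graph, labels)
  terms <- ifelse(cw$W > 0, cw$w / cw$W - (cw$s / (2 * cw$W))^2, 0)
  score_result(terms, cw)
}

#' Simplified weight local modularity (the selection objective)
#'
#' `WLM^s = sum_k w_k / (w_k + w_k_out)`: the fraction of each class's
#' incident edge weight that stays inside the class, summed over classes.
#' Bounded by the class count C, reaching C exactly when no between-class
#' edges exist (and every class has internal weight).
#'
#' @inheritParams community_weights
#' @return A `"modularity_score"` with `value` in `[0, C]`.
#' @export
wlm_s <- function(graph, labels) {
  cw <- community_weights(graph, labels)
  terms <- ifelse(cw$W > 0, cw$w / cw$W, 0)
  score_result(terms, cw)
}

#' Score a gene subset by the WLM^s of its weighted sample graph
#'
#' Builds the weighted sample graph of the dataset restricted to `subset`
#' and returns its [wlm_s()] value. This is the single scoring entry point
#' the greedy selector maximizes.
#'
#' @param dataset A [labeled_dataset()].
#' @param subset Gene indices or identifiers.
#' @param k Number of neighbours for the graph.
#' @return Numeric scalar in `[0, C]`.
#' @export
wlms_for_subset <- function(dataset, subset, k) {
  D <- squared_distances(dataset$x, subset)
  wlms_fast(unclass(D), class_index_list(dataset$labels),
            clamp_k(k, nrow(D)))
}

class_index_list <- function(labels) {
  labels <- factor(as.vector(labels))
  lapply(levels(labels), function(cl) which(labels == cl))
}

# Hot path shared by wlms_for_subset and the selector: squared-distance
# matrix in, WLM^s out, no intermediate objects beyond the masked affinity.
wlms_fast <- function(D, class_idx, k) {
  mask <- knn_mask(D, k)
  A <- matrix(0, nrow(D), ncol(D))
  A[mask] <- exp(-sqrt(D[mask]))
  total <- 0
  for (idx in class_idx) {
    s <- sum(A[idx, , drop = FALSE])
    if (s > 0) {
      w <- sum(A[idx, idx, drop = FALSE]) / 2
      total <- total + w / (s - w)
    }
  }
  total
}

#' Serialize a modularity score as JSON
#'
#' @param score A `"modularity_score"`.
#' @param path Optional output path; `NULL` returns the JSON string.
#' @return JSON string (invisibly when written to `path`).
#' @export
score_to_json <- function(score, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("score_to_json needs the jsonlite package", call. = FALSE)
  payload <- list(value = score$value, terms = as.list(score$terms),
                  community_weights = score$weights)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
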