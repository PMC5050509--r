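# Sequential forward greedy selection maximizing WLM^s. The first gene is
# the single-gene argmax; each later step scores every remaining candidate
# on the incrementally extended distance matrix and accepts the best one
# unless its score gain falls below theta (the sub-threshold candidate is
# rejected, so the reported subset never ends on an uninformative gene).
# Ties always resolve to the smallest gene index, which makes runs
# bit-for-bit reproducible.

#' Selection configuration
#'
#' @param k Neighbour count for the weighted sample graph (default 7).
#' @param lambda_max Maximum number of genes to select (default 15).
#' @param theta Minimum WLM^s increment required to accept another gene
#'   (default 0.02); only active when `stop_rule = "increment"`.
#' @param candidate_pool Optional restriction of the search to a set of
#'   gene indices or identifiers; `NULL` means all genes.
#' @param stop_rule `"increment"` stops when the best candidate's gain
#'   drops below `theta`; `"cap-only"` ignores `theta` and always runs to
#'   `lambda_max` (or pool exhaustion), which is useful for fixed-length
#'   ranking curves.
#' @return A list of class `"selection_config"`.
#' @export
selection_config <- function(k = 7, lambda_max = 15, theta = 0.02,
                             candidate_pool = NULL,
                             stop_rule = c("increment", "cap-only")) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(lambda_max >= 1, theta >= 0, k >= 1)
  structure(list(k = as.integer(k), lambda_max = as.integer(lambda_max),
                 theta = theta, candidate_pool = candidate_pool,
                 stop_rule = stop_rule),
            class = "selection_config")
}

resolve_pool <- function(dataset, config) {
  if (is.null(config$candidate_pool)) seq_len(ncol(dataset$x))
  else sort(unique(gene_indices(dataset$x, config$candidate_pool)))
}

#' Pick the first gene of the forward search
#'
#' Returns the gene whose single-gene weighted sample graph has the
#' largest WLM^s; ties go to the smallest gene index.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [selection_config()].
#' @return Integer gene (column) index.
#' @export
select_first_gene <- function(dataset, config = selection_config()) {
  pool <- resolve_pool(dataset, config)
  if (length(pool) == 0L) stop("empty candidate pool", call. = FALSE)
  x <- unclass_matrix(dataset$x)
  cls <- class_index_list(dataset$labels)
  k <- clamp_k(config$k, nrow(x))
  scores <- vapply(pool, function(g) {
    v <- x[, g]
    D <- outer(v, v, "-")^2
    wlms_fast(D, cls, k)
  }, numeric(1))
  pool[which.max(scores)]   # which.max returns the first maximum
}

#' One greedy extension step
#'
#' Scores `current` plus each remaining candidate (reusing the incremental
#' squared-distance state) and returns the best candidate and the WLM^s it
#' achieves. Neither `current` nor `state` is modified.
#'
#' @param dataset A [labeled_dataset()].
#' @param current Integer vector of already-selected gene indices.
#' @param state The `distance_state` for `current`.
#' @param config A [selection_config()].
#' @return List with `gene` (index) and `score`, or `NULL` when no
#'   candidates remain.
#' @export
greedy_step <- function(dataset, current, state, config = selection_config()) {
  pool <- setdiff(resolve_pool(dataset, config), current)
  if (length(pool) == 0L) return(NULL)
  x <- unclass_matrix(dataset$x)
  cls <- class_index_list(dataset$labels)
  k <- clamp_k(config$k, nrow(x))
  D0 <- unclass(state)
  scores <- vapply(pool, function(g) {
    v <- x[, g]
    wlms_fast(D0 + outer(v, v, "-")^2, cls, k)
  }, numeric(1))
  best <- which.max(scores)
  list(gene = pool[best], score = scores[best])
}

#' Forward greedy gene-subset selection by weight local modularity
#'
#' Runs the full search: the best single gene first, then repeated
#' [greedy_step()] extensions until (a) the best candidate's increment is
#' below `theta` (that candidate is not added), (b) `lambda_max` genes are
#' selected, or (c) the candidate pool is exhausted.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [selection_config()].
#' @return An object of class `"wlmgs_selection"`: list with `genes`
#'   (indices in selection order), `gene_ids`, `scores` (WLM^s after each
#'   acceptance), `increments` (first differences; the first entry is the
#'   first gene's score), `stopped_by` (`"theta"`, `"lambda"` or
#'   `"pool-exhausted"`), and the `config`.
#' @export
wlmgs_select <- function(dataset, config = selection_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- dataset$x
  g1 <- select_first_gene(dataset, config)
  state <- squared_distances(x, g1)
  genes <- g1
  scores <- wlms_for_subset(dataset, g1, config$k)
  stopped_by <- "pool-exhausted"
  while (length(genes) < config$lambda_max) {
    step <- greedy_step(dataset, genes, state, config)
    if (is.null(step)) { stopped_by <- "pool-exhausted"; break }
    inc <- step$score - scores[length(scores)]
    if (config$stop_rule == "increment" && inc < config$theta) {
      stopped_by <- "theta"
      break
    }
    state <- extend_distances(state, x, step$gene)
    genes <- c(genes, step$gene)
    scores <- c(scores, step$score)
  }
  if (length(genes) == config$lambda_max) stopped_by <- "lambda"
  structure(list(genes = genes,
                 gene_ids = colnames(x)[genes],
                 scores = scores,
                 increments = c(scores[1], diff(scores)),
                 stopped_by = stopped_by,
                 config = config),
            class = "wlmgs_selection")
}

#' @export
print.wlmgs_selection <- function(x, ...) {
  cat(sprintf("WLMGS selection: %d genes (stopped by %s)\n",
              length(x$genes), x$stopped_by))
  print(data.frame(gene = x$gene_ids, wlms = round(x$scores, 4),
                   increment = round(x$increments, 4)))
  invisible(x)
}

#' Serialize a selection result as JSON
#'
#' @param result A `"wlmgs_selection"`.
#' @param path Optional output path; `NULL` returns the JSON string.
#' @return JSON string (invisibly when written to `path`).
#' @export
selection_to_json <- function(result, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("selection_to_json needs the jsonlite package", call. = FALSE)
  payload <- list(genes = result$gene_ids, gene_indices = result$genes,
                  scores = result$scores, increments = result$increments,
                  stopped_by = result$stopped_by,
                  config = unclass(result$config))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
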