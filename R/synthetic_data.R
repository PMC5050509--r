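# Synthetic class-structured expression data with known ground truth, so
# the whole selection pipeline can be exercised and judged offline. The
# generator emulates the small-m / large-n regime of tumour microarray
# panels: tens of samples, hundreds to thousands of genes, 2-5 classes,
# optional class imbalance and outlier samples. It makes no attempt to
# mimic platform noise (no intensity-dependent variance, no batch
# effects).

#' Specification of a synthetic labelled expression dataset
#'
#' Informative genes get class-dependent Gaussian means: class centroids
#' sit on an equidistant simplex (unit pairwise distance), cycled across
#' the informative genes and scaled by `effect_size`, so multi-class
#' separation is symmetric and no class pair is favoured. Noise genes are
#' class-independent standard normals. Redundant genes are near-copies of
#' informative genes (jitter SD 0.1). Outlier samples are overdrawn at
#' SD 5 on every gene while keeping their true class label.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Integer vector of class sizes (imbalance
#'   allowed).
#' @param n_informative Number of informative genes.
#' @param n_noise Number of pure-noise genes.
#' @param effect_size Class-mean separation in within-class SD units;
#'   a scalar, or one value per informative gene.
#' @param n_redundant Number of jittered copies of informative genes.
#' @param n_outlier_samples Number of samples redrawn as outliers.
#' @param within_class_clusters Optional sub-cluster count per class;
#'   sub-clusters shift informative-gene means by +/- 1 within a class.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 2,
                           samples_per_class = rep(30, n_classes),
                           n_informative = 5, n_noise = 95,
                           effect_size = 2, n_redundant = 0,
                           n_outlier_samples = 0,
                           within_class_clusters = NULL, seed = 1) {
  stopifnot(n_classes >= 2, length(samples_per_class) == n_classes,
            all(samples_per_class >= 1), n_informative >= 0, n_noise >= 0,
            n_redundant >= 0, n_outlier_samples >= 0, all(effect_size >= 0),
            n_informative + n_noise + n_redundant >= 1)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant genes need informative genes to copy", call. = FALSE)
  if (length(effect_size) != 1 && length(effect_size) != n_informative)
    stop("effect_size must be scalar or one value per informative gene",
         call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size,
                 n_redundant = as.integer(n_redundant),
                 n_outlier_samples = as.integer(n_outlier_samples),
                 within_class_clusters = within_class_clusters,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Vertices of a regular (C-1)-simplex in R^(C-1), centred at the origin,
# with unit pairwise distance between vertices.
simplex_vertices <- function(C) {
  if (C == 1) return(matrix(0, 1, 1))
  V <- diag(C)                      # unit-pairwise-distance after scaling
  V <- V - matrix(1 / C, C, C) %*% V
  V <- V / sqrt(2)                  # |e_i - e_j| = sqrt(2) -> 1
  # drop to the C-1 dimensions actually spanned (isometric projection)
  sv <- svd(V)
  V %*% sv$v[, seq_len(C - 1), drop = FALSE]
}

#' Generate a synthetic labelled dataset with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [labeled_dataset()]), `truth` (integer
#'   index sets `informative`, `redundant`, `noise` into the gene
#'   columns), `outlier_samples` (row indices), and the `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  C <- spec$n_classes
  m <- sum(spec$samples_per_class)
  labels <- factor(rep(paste0("class", seq_len(C)), spec$samples_per_class))
  effect <- rep_len(spec$effect_size, max(spec$n_informative, 1L))
  verts <- simplex_vertices(C)                 # C x (C-1)
  ndim <- ncol(verts)

  inform <- NULL
  if (spec$n_informative > 0) {
    # cycle the simplex coordinates over genes; gene j uses axis
    # ((j-1) mod (C-1)) + 1, scaled by that gene's effect size
    axis <- ((seq_len(spec$n_informative) - 1L) %% ndim) + 1L
    mu <- verts[as.integer(labels), axis, drop = FALSE] *
      rep(effect[seq_len(spec$n_informative)], each = m)
    if (!is.null(spec$within_class_clusters)) {
      ncl <- spec$within_class_clusters
      sub <- unlist(lapply(spec$samples_per_class, function(s)
        sample(rep_len(seq_len(ncl), s))))
      mu <- mu + (2 * (sub %% 2) - 1)          # +/- 1 sub-cluster shift
    }
    inform <- mu + matrix(stats::rnorm(m * spec$n_informative), m)
  }
  noise <- if (spec$n_noise > 0)
    matrix(stats::rnorm(m * spec$n_noise), m) else NULL
  redundant <- NULL
  if (spec$n_redundant > 0) {
    src <- rep_len(seq_len(spec$n_informative), spec$n_redundant)
    redundant <- inform[, src, drop = FALSE] +
      matrix(stats::rnorm(m * spec$n_redundant, sd = 0.1), m)
  }

  x <- cbind(inform, redundant, noise)
  n_inf <- spec$n_informative
  n_red <- spec$n_redundant
  truth <- list(
    informative = seq_len(n_inf),
    redundant = if (n_red > 0) n_inf + seq_len(n_red) else integer(0),
    noise = if (spec$n_noise > 0)
      n_inf + n_red + seq_len(spec$n_noise) else integer(0))

  outliers <- integer(0)
  if (spec$n_outlier_samples > 0) {
    outliers <- sort(sample.int(m, spec$n_outlier_samples))
    x[outliers, ] <- matrix(stats::rnorm(length(outliers) * ncol(x), sd = 5),
                            length(outliers))
  }
  dimnames(x) <- list(paste0("s", seq_len(m)), paste0("g", seq_len(ncol(x))))
  list(dataset = labeled_dataset(x, labels), truth = truth,
       outlier_samples = outliers, spec = spec)
}

#' Named fixture graphs for the modularity scores
#'
#' Small labelled graphs with hand-computable community weights:
#' \describe{
#'   \item{`isolated-pairs`}{4 nodes, one internal edge per class
#'     (weight 1 each); WLM^s = 2.}
#'   \item{`path-4`}{the 4-node path with weights `exp(-2)`, `exp(-1)`,
#'     `exp(-2)` and a 2+2 class split, as arises from 1-D samples
#'     0, 2, 3, 5 under 1-NN union.}
#'   \item{`two-triangles`}{two disjoint unit-weight triangles, one class
#'     each.}
#'   \item{`random`}{an Erdos-Renyi-style weighted graph with uniformly
#'     random labels, reproducible from `seed`.}
#' }
#'
#' @param name One of `"isolated-pairs"`, `"path-4"`, `"two-triangles"`,
#'   `"random"`.
#' @param m,C,seed Size, class count and seed for `name = "random"`.
#' @return List with `graph` (a `"wsg"`) and `labels` (factor).
#' @export
fixture_graph <- function(name, m = 10, C = 2, seed = 1) {
  known <- c("isolated-pairs", "path-4", "two-triangles", "random")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (name == "random") {
    set.seed(seed)
    A <- matrix(0, m, m)
    ut <- upper.tri(A)
    present <- ut & matrix(stats::runif(m * m) < 0.4, m, m)
    A[present] <- stats::runif(sum(present))
    A <- A + t(A)
    labels <- sample(paste0("class", seq_len(C)), m, replace = TRUE)
    labels[seq_len(C)] <- paste0("class", seq_len(C))  # every class inhabited
    labels <- factor(labels)
    return(list(graph = structure(list(A = A, k = NA_integer_,
                                       subset = integer(0)), class = "wsg"),
                labels = labels))
  }
  fix <- switch(name,
    "isolated-pairs" = list(
      edges = rbind(c(1, 2, 1), c(3, 4, 1)),
      labels = c("A", "A", "B", "B")),
    "path-4" = list(
      edges = rbind(c(1, 2, exp(-2)), c(2, 3, exp(-1)), c(3, 4, exp(-2))),
      labels = c("A", "A", "B", "B")),
    "two-triangles" = list(
      edges = rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1),
                    c(4, 5, 1), c(4, 6, 1), c(5, 6, 1)),
      labels = c("A", "A", "A", "B", "B", "B")))
  n <- length(fix$labels)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(fix$edges))) {
    i <- fix$edges[r, 1]; j <- fix$edges[r, 2]; w <- fix$edges[r, 3]
    A[i, j] <- w; A[j, i] <- w
  }
  list(graph = structure(list(A = A, k = NA_integer_, subset = integer(0)),
                         class = "wsg"),
       labels = factor(fix$labels))
}

#' Write a generated dataset to delimited files
#'
#' @param gen Output of [generate_dataset()].
#' @param expr_path Expression TSV/CSV path.
#' @param labels_path Two-column label file path.
#' @param truth_path Optional JSON path for the ground-truth gene sets.
#' @return `gen`, invisibly.
#' @export
write_dataset <- function(gen, expr_path, labels_path, truth_path = NULL) {
  write_expression(gen$dataset$x, expr_path)
  utils::write.table(
    data.frame(sample = rownames(gen$dataset$x),
               label = as.character(gen$dataset$labels)),
    labels_path, sep = sniff_sep(labels_path), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  if (!is.null(truth_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing ground truth needs the jsonlite package", call. = FALSE)
    jsonlite::write_json(gen$truth, truth_path)
  }
  invisible(gen)
}
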