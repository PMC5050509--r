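# The cross-validated evaluation protocol: per-fold normalization and
# selection on the training portion only, 1-NN and RBF-SVM accuracy on the
# held-out fold, and a frequency-consensus subset across folds. Also holds
# the k-means within-class objective used to check that high WLM^s tracks
# low J(C, mu).

#' Stratified cross-validation folds
#'
#' Samples of each class are shuffled and dealt round-robin into
#' `n_folds` test folds, preserving per-class proportions within one
#' sample. Classes with fewer samples than folds trigger a fallback to
#' plain shuffled folds with a warning.
#'
#' @param labels Per-sample class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed; identical seeds give identical folds.
#' @param stratify Set `FALSE` to force plain shuffled folds.
#' @return List of `n_folds` lists, each with integer `train` and `test`
#'   index vectors partitioning the samples.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1,
                             stratify = TRUE) {
  labels <- factor(as.vector(labels))
  m <- length(labels)
  if (n_folds > m)
    stop(sprintf("%d folds for %d samples", n_folds, m), call. = FALSE)
  if (stratify && any(table(labels) < n_folds)) {
    warning("some class has fewer samples than folds; ",
            "falling back to unstratified folds", call. = FALSE)
    stratify <- FALSE
  }
  assign_fold <- local({
    set.seed(seed)
    fold <- integer(m)
    if (stratify) {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(m)] <- rep_len(seq_len(n_folds), m)
    }
    fold
  })
  lapply(seq_len(n_folds), function(f)
    list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' Nearest-neighbour classification (1-NN, Euclidean)
#'
#' Each test sample receives the label of its Euclidean-nearest training
#' sample; distance ties go to the smallest training index.
#'
#' @param train_x Training matrix (samples x genes).
#' @param train_y Training labels.
#' @param test_x Test matrix sharing the gene columns of `train_x`.
#' @return Factor of predicted labels, one per test row.
#' @export
one_nn_classify <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(unclass_matrix(train_x))
  test_x <- as.matrix(unclass_matrix(test_x))
  stopifnot(nrow(train_x) >= 1, ncol(train_x) == ncol(test_x))
  train_y <- factor(as.vector(train_y))
  cp <- tcrossprod(test_x, train_x)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cp
  nearest <- apply(d2, 1, which.min)    # first minimum = smallest index
  factor(train_y[nearest], levels = levels(train_y))
}

#' RBF-kernel support-vector classification
#'
#' A soft-margin SVM with radial kernel at the given cost (default
#' C = 100), multiclass handled one-vs-one. The kernel bandwidth is
#' `gamma = 1 / (n_genes * var(x))` with `var(x)` the overall variance of
#' the training values, falling back to `1 / n_genes` for constant input.
#' A degenerate single-class training fold predicts that class with a
#' warning.
#'
#' @param train_x Training matrix (samples x genes).
#' @param train_y Training labels.
#' @param test_x Test matrix sharing the gene columns of `train_x`.
#' @param cost Soft-margin cost C.
#' @return Factor of predicted labels, one per test row.
#' @export
svm_classify <- function(train_x, train_y, test_x, cost = 100) {
  train_x <- as.matrix(unclass_matrix(train_x))
  test_x <- as.matrix(unclass_matrix(test_x))
  train_y <- factor(as.vector(train_y))
  if (nlevels(droplevels(train_y)) < 2) {
    warning("single-class training fold; predicting that class",
            call. = FALSE)
    return(factor(rep(as.character(train_y[1]), nrow(test_x)),
                  levels = levels(train_y)))
  }
  v <- stats::var(as.vector(train_x))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(train_x) * v)
           else 1 / ncol(train_x)
  fit <- e1071::svm(train_x, train_y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  stats::predict(fit, test_x)
}

classify_with <- function(classifier, train_x, train_y, test_x) {
  switch(classifier,
         "1nn" = one_nn_classify(train_x, train_y, test_x),
         "svm" = svm_classify(train_x, train_y, test_x),
         stop("unknown classifier: ", classifier, call. = FALSE))
}

#' Cross-validated gene selection and accuracy estimation
#'
#' For every fold: fit z-score statistics on the training samples only,
#' normalize train and test with them, run [wlmgs_select()] on the
#' training portion, and score both classifiers on the held-out fold in
#' the selected gene space. Genes are then ranked by how many folds
#' selected them (ties by mean selection rank, then index); the consensus
#' subset takes the top genes at the most common fold-subset size.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [selection_config()].
#' @param n_folds Folds per repeat (default 10).
#' @param repeats Number of full CV repeats with distinct fold seeds.
#' @param seed Base seed for fold assignment.
#' @param classifiers Character vector among `"1nn"`, `"svm"`.
#' @param normalize `"per-fold"` (training statistics only, the default)
#'   or `"global"` (one normalization of the full matrix up front).
#' @param stratify Passed to [stratified_folds()].
#' @return An object of class `"wlmgs_cv"`: list with `folds` (per-fold
#'   selected genes and accuracies), `frequency` (named selection counts
#'   over all folds), `consensus_genes`, `consensus_size`,
#'   `mean_fold_subset_size`, `mean_accuracy` (named per classifier), and
#'   a config echo.
#' @export
cross_validated_selection <- function(dataset, config = selection_config(),
                                      n_folds = 10, repeats = 1, seed = 1,
                                      classifiers = c("1nn", "svm"),
                                      normalize = c("per-fold", "global"),
                                      stratify = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  normalize <- match.arg(normalize)
  x_raw <- dataset$x
  if (normalize == "global") x_raw <- zscore_normalize(x_raw)
  fold_entries <- list()
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(dataset$labels, n_folds,
                              seed = seed + (r - 1L), stratify = stratify)
    for (f in seq_along(folds)) {
      tr <- folds[[f]]$train; te <- folds[[f]]$test
      if (normalize == "per-fold") {
        zs <- zscore_fit(x_raw[tr, , drop = FALSE])
        xtr <- zscore_normalize(x_raw[tr, , drop = FALSE], zs)
        xte <- zscore_normalize(x_raw[te, , drop = FALSE], zs)
      } else {
        xtr <- x_raw[tr, , drop = FALSE]
        xte <- x_raw[te, , drop = FALSE]
      }
      ds_tr <- labeled_dataset(xtr, dataset$labels[tr])
      sel <- wlmgs_select(ds_tr, config)
      acc <- vapply(classifiers, function(cl) {
        pred <- classify_with(cl, xtr[, sel$genes, drop = FALSE],
                              dataset$labels[tr],
                              xte[, sel$genes, drop = FALSE])
        mean(as.character(pred) == as.character(dataset$labels[te]))
      }, numeric(1))
      fold_entries[[length(fold_entries) + 1L]] <-
        list(repeat_id = r, fold = f, test = te,
             genes = sel$genes, gene_ids = sel$gene_ids,
             stopped_by = sel$stopped_by, accuracy = acc)
    }
  }
  all_genes <- unlist(lapply(fold_entries, `[[`, "genes"))
  freq <- table(all_genes)
  mean_rank <- tapply(
    unlist(lapply(fold_entries, function(e) seq_along(e$genes))),
    all_genes, mean)
  ord <- order(-as.vector(freq), as.vector(mean_rank),
               as.integer(names(freq)))
  ranked <- as.integer(names(freq))[ord]
  sizes <- vapply(fold_entries, function(e) length(e$genes), integer(1))
  size_tab <- table(sizes)
  consensus_size <- as.integer(names(size_tab)[which.max(size_tab)])
  acc_mat <- do.call(rbind, lapply(fold_entries, `[[`, "accuracy"))
  structure(list(
    folds = fold_entries,
    frequency = stats::setNames(as.integer(freq)[ord],
                                colnames(dataset$x)[ranked]),
    ranked_genes = ranked,
    consensus_genes = ranked[seq_len(min(consensus_size, length(ranked)))],
    consensus_size = consensus_size,
    mean_fold_subset_size = mean(sizes),
    mean_accuracy = colMeans(acc_mat),
    config = list(selection = config, n_folds = n_folds, repeats = repeats,
                  seed = seed, classifiers = classifiers,
                  normalize = normalize, stratify = stratify)),
    class = "wlmgs_cv")
}

#' @export
print.wlmgs_cv <- function(x, ...) {
  cat(sprintf("WLMGS cross-validation: %d fold runs\n", length(x$folds)))
  cat(sprintf("mean fold subset size: %.2f; consensus size: %d\n",
              x$mean_fold_subset_size, x$consensus_size))
  cat("mean accuracy:",
      paste(sprintf("%s = %.4f", names(x$mean_accuracy), x$mean_accuracy),
            collapse = ", "), "\n")
  cat("consensus genes:", paste(x$consensus_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated accuracy as a function of subset size
#'
#' For each prefix of a ranked gene list, estimates CV accuracy with the
#' chosen classifier using only those genes. Normalization is per-fold on
#' the training samples.
#'
#' @param dataset A [labeled_dataset()].
#' @param ranked_genes Gene indices or identifiers, best first.
#' @param classifier `"1nn"` or `"svm"`.
#' @param max_genes Longest prefix to evaluate.
#' @param n_folds,seed,stratify Passed to [stratified_folds()].
#' @return Data frame with columns `n_genes` and `accuracy`.
#' @export
accuracy_curve <- function(dataset, ranked_genes, classifier = "1nn",
                           max_genes = length(ranked_genes), n_folds = 10,
                           seed = 1, stratify = TRUE) {
  genes <- gene_indices(dataset$x, ranked_genes)
  if (length(genes) == 0L) stop("ranked gene list is empty", call. = FALSE)
  gmax <- min(max_genes, length(genes))
  folds <- stratified_folds(dataset$labels, n_folds, seed = seed,
                            stratify = stratify)
  acc <- vapply(seq_len(gmax), function(g) {
    sub <- genes[seq_len(g)]
    fold_acc <- vapply(folds, function(fd) {
      zs <- zscore_fit(dataset$x[fd$train, , drop = FALSE])
      xtr <- zscore_normalize(dataset$x[fd$train, , drop = FALSE], zs)
      xte <- zscore_normalize(dataset$x[fd$test, , drop = FALSE], zs)
      pred <- classify_with(classifier, xtr[, sub, drop = FALSE],
                            dataset$labels[fd$train],
                            xte[, sub, drop = FALSE])
      mean(as.character(pred) == as.character(dataset$labels[fd$test]))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  data.frame(n_genes = seq_len(gmax), accuracy = acc)
}

#' Within-class k-means objective
#'
#' `J(C, mu) = sum_i || x_i - mu_{c(i)} ||^2` with class-conditional means
#' as the fixed cluster centres (no reassignment). The squared form is the
#' standard k-means objective; `squared = FALSE` sums plain Euclidean
#' distances instead for sensitivity checks.
#'
#' @param x Matrix of samples x genes (any gene subset already applied).
#' @param labels Per-sample class labels defining the clusters.
#' @param squared Use squared distances (default `TRUE`).
#' @return Numeric scalar.
#' @export
kmeans_objective <- function(x, labels, squared = TRUE) {
  x <- as.matrix(unclass_matrix(x))
  labels <- factor(as.vector(labels))
  stopifnot(length(labels) == nrow(x))
  total <- 0
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    mu <- colMeans(x[idx, , drop = FALSE])
    d2 <- rowSums(sweep(x[idx, , drop = FALSE], 2, mu, "-")^2)
    total <- total + if (squared) sum(d2) else sum(sqrt(d2))
  }
  total
}
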