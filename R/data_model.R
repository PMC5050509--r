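# Expression-data containers, delimited-text I/O and per-gene z-scoring.
#
# The canonical in-memory layout is a numeric matrix with samples in rows
# and genes in columns (distances are between samples, so samples-major
# access dominates everywhere downstream).

#' Validate and tag a samples-by-genes expression matrix
#'
#' An expression matrix is an ordinary numeric matrix with unique, non-empty
#' row names (sample identifiers) and column names (gene identifiers) and no
#' missing or non-finite values.
#'
#' @param x Numeric matrix, samples in rows, genes in columns. Row and
#'   column names are required and must be unique.
#' @return `x`, validated, with class `"expression_matrix"` prepended.
#' @export
as_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs sample (row) and gene (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', gene '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  class(x) <- c("expression_matrix", class(unclass(x)))
  x
}

#' Read a delimited expression table
#'
#' Reads a TSV or CSV file with one header line and one identifier column
#' into a samples-by-genes [as_expression_matrix()] matrix. The delimiter is
#' sniffed from the file extension (`.csv` means comma, anything else tab)
#' unless given explicitly.
#'
#' @param path Path to the file.
#' @param genes_in_rows If `TRUE` the file stores genes in rows and samples
#'   in columns; the result is transposed to the canonical orientation.
#' @param sep Field delimiter; `NULL` (default) sniffs from the extension.
#' @return An `expression_matrix` in samples x genes orientation.
#' @export
read_expression <- function(path, genes_in_rows = FALSE, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = dimnames(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric cell '%s' at row '%s', column '%s' of %s",
      as.matrix(df)[bad[1], bad[2]], rownames(df)[bad[1]],
      colnames(df)[bad[2]], path), call. = FALSE)
  }
  if (genes_in_rows) vals <- t(vals)
  as_expression_matrix(vals)
}

#' Write an expression matrix back to delimited text
#'
#' Values are printed at full precision (17 significant digits) so that a
#' read/write cycle round-trips exactly.
#'
#' @param x An expression matrix (samples x genes).
#' @param path Output path; extension picks the delimiter as in
#'   [read_expression()].
#' @param sep Field delimiter; `NULL` sniffs from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  chr <- format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE)
  df <- as.data.frame(chr, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-column sample-to-label file
#'
#' @param path Path to a delimited file whose first column is the sample
#'   identifier and second column the class label.
#' @param header Whether the file has a header line (never auto-detected).
#' @param sep Field delimiter; `NULL` sniffs from the extension.
#' @return Named character vector of labels, names are sample identifiers.
#' @export
read_labels <- function(path, header = FALSE, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2)
    stop("label file must have two columns: sample id, label", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Bundle an expression matrix with per-sample class labels
#'
#' Labels given as a named vector are reordered to the matrix's sample
#' order; samples missing a label are an error, labels for unknown samples
#' a warning. At least two classes, each with at least one sample, are
#' required.
#'
#' @param x An expression matrix (samples x genes).
#' @param labels Class labels: either one per matrix row (in row order) or
#'   a named vector keyed by sample identifier.
#' @return An object of class `"labeled_dataset"`: list with elements `x`
#'   (the matrix) and `labels` (a factor, one level per class).
#' @export
labeled_dataset <- function(x, labels) {
  x <- as_expression_matrix(unclass_matrix(x))
  if (!is.null(names(labels)) && any(names(labels) != "")) {
    missing <- setdiff(rownames(x), names(labels))
    if (length(missing))
      stop("samples missing from labels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    extra <- setdiff(names(labels), rownames(x))
    if (length(extra))
      warning("labels for unknown samples ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    labels <- labels[rownames(x)]
  }
  if (length(labels) != nrow(x))
    stop(sprintf("%d labels for %d samples", length(labels), nrow(x)),
         call. = FALSE)
  labels <- factor(as.vector(labels))
  if (nlevels(labels) < 2)
    stop("at least two classes are required (got ",
         nlevels(labels), ")", call. = FALSE)
  structure(list(x = x, labels = labels), class = "labeled_dataset")
}

unclass_matrix <- function(x) {
  class(x) <- setdiff(class(x), "expression_matrix")
  x
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d genes, %d classes (%s)\n",
              nrow(x$x), ncol(x$x), nlevels(x$labels),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Fit per-gene z-score statistics
#'
#' Computes each gene's mean and sample standard deviation (denominator
#' m - 1). Genes with zero standard deviation are flagged as constant;
#' their scale is set to 1 so that normalization maps them to all-zero
#' columns instead of dividing by zero.
#'
#' @param x An expression matrix with at least two samples.
#' @return List with `center`, `scale` (named per gene) and
#'   `constant_genes` (character vector of flagged gene ids).
#' @export
zscore_fit <- function(x) {
  x <- unclass_matrix(x)
  if (nrow(x) < 2)
    stop("z-scoring needs at least two samples", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  constant <- colnames(x)[scale == 0]
  scale[scale == 0] <- 1
  list(center = center, scale = scale, constant_genes = constant)
}

#' Z-score normalize each gene to mean 0 and standard deviation 1
#'
#' With `stats = NULL` the statistics are fit on `x` itself. Passing the
#' statistics of a training set normalizes held-out samples with the
#' training means and standard deviations, which is how the
#' cross-validation harness avoids leaking test-fold information.
#' Constant genes map to all-zero columns and are listed in the
#' `"constant_genes"` attribute of the result.
#'
#' @param x An expression matrix.
#' @param stats Optional statistics from [zscore_fit()]; `NULL` fits on `x`.
#' @return The normalized matrix with a `"constant_genes"` attribute.
#' @export
zscore_normalize <- function(x, stats = NULL) {
  stats <- stats %||% zscore_fit(x)
  out <- sweep(sweep(unclass_matrix(x), 2, stats$center, "-"),
               2, stats$scale, "/")
  out <- as_expression_matrix(out)
  attr(out, "constant_genes") <- stats$constant_genes
  out
}

#' Resolve gene identifiers or indices to column indices
#'
#' @param x An expression matrix.
#' @param genes Integer indices or gene identifiers.
#' @return Integer vector of column indices, in the given order.
#' @export
gene_indices <- function(x, genes) {
  if (is.character(genes)) {
    idx <- match(genes, colnames(x))
    if (anyNA(idx))
      stop("unknown genes: ", paste(genes[is.na(idx)], collapse = ", "),
           call. = FALSE)
    idx
  } else {
    idx <- as.integer(genes)
    if (any(idx < 1L | idx > ncol(x)))
      stop("gene index out of range", call. = FALSE)
    idx
  }
}
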