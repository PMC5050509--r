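# Independent oracles used across the suite. These deliberately share no
# code with the package: everything is an explicit loop over edges or
# samples so disagreement points at the vectorized implementation.

# Edge-enumeration oracle for the three modularity scores.
oracle_scores <- function(A, labels) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  acc <- list()
  for (cl in cls)
    acc[[cl]] <- c(w = 0, wout = 0, s = 0, me = 0, be = 0, d = 0)
  m <- nrow(A)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (A[i, j] <= 0) next
    wij <- A[i, j]
    ci <- labels[i]; cj <- labels[j]
    acc[[ci]]["s"] <- acc[[ci]]["s"] + wij
    acc[[cj]]["s"] <- acc[[cj]]["s"] + wij
    acc[[ci]]["d"] <- acc[[ci]]["d"] + 1
    acc[[cj]]["d"] <- acc[[cj]]["d"] + 1
    if (ci == cj) {
      acc[[ci]]["w"] <- acc[[ci]]["w"] + wij
      acc[[ci]]["me"] <- acc[[ci]]["me"] + 1
    } else {
      acc[[ci]]["wout"] <- acc[[ci]]["wout"] + wij
      acc[[cj]]["wout"] <- acc[[cj]]["wout"] + wij
      acc[[ci]]["be"] <- acc[[ci]]["be"] + 1
      acc[[cj]]["be"] <- acc[[cj]]["be"] + 1
    }
  }
  lm <- wlm <- wlms <- 0
  for (cl in cls) {
    a <- acc[[cl]]
    Wk <- a["w"] + a["wout"]
    Mk <- a["me"] + a["be"]
    if (Mk > 0) lm <- lm + a["me"] / Mk - (a["d"] / (2 * Mk))^2
    if (Wk > 0) {
      wlm <- wlm + a["w"] / Wk - (a["s"] / (2 * Wk))^2
      wlms <- wlms + a["w"] / Wk
    }
  }
  list(lm = unname(lm), wlm = unname(wlm), wlms = unname(wlms), acc = acc)
}

# Sort-with-index oracle for k nearest neighbours of one sample.
oracle_knn_one <- function(d_row, self, k) {
  cand <- setdiff(seq_along(d_row), self)
  cand[order(d_row[cand], cand)][seq_len(k)]
}

# Exhaustive-scan 1-NN oracle.
oracle_1nn <- function(train_x, train_y, test_x) {
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- apply(train_x, 1, function(r) sqrt(sum((r - test_x[i, ])^2)))
    out[i] <- as.character(train_y[which.min(d)])
  }
  out
}

# Small labelled dataset for quick pipeline checks.
tiny_dataset <- function(seed = 1, m_per_class = 8, n_genes = 5,
                         effect = 2) {
  set.seed(seed)
  x <- matrix(rnorm(2 * m_per_class * n_genes), 2 * m_per_class)
  x[seq_len(m_per_class), 1] <- x[seq_len(m_per_class), 1] + effect
  dimnames(x) <- list(paste0("s", seq_len(nrow(x))),
                      paste0("g", seq_len(n_genes)))
  labeled_dataset(x, rep(c("A", "B"), each = m_per_class))
}

expect_same_selection <- function(a, b) {
  expect_identical(a$genes, b$genes)
  expect_identical(a$scores, b$scores)
  expect_identical(a$increments, b$increments)
  expect_identical(a$stopped_by, b$stopped_by)
}
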