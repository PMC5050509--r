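separating_dataset <- function() {
  # gene 1 separates the classes at distance 10; gene 2 is i.i.d. noise
  set.seed(5)
  x <- cbind(g1 = c(rep(0, 6), rep(10, 6)) + rnorm(12, sd = 0.1),
             g2 = rnorm(12))
  rownames(x) <- paste0("s", 1:12)
  labeled_dataset(x, rep(c("A", "B"), each = 6))
}

test_that("the first gene is the single-gene WLM^s argmax with index ties", {
  ds <- separating_dataset()
  cfg <- selection_config(k = 1)
  expect_equal(select_first_gene(ds, cfg), 1L)

  # duplicated columns give identical scores: lower index wins
  xdup <- cbind(ds$x[, c(2, 2)], ds$x[, 1])
  colnames(xdup) <- paste0("g", 1:3)
  dsd <- labeled_dataset(xdup, ds$labels)
  expect_equal(select_first_gene(dsd, selection_config(k = 1,
                 candidate_pool = 1:2)), 1L)

  # singleton pool returns its only member regardless of score
  expect_equal(select_first_gene(ds, selection_config(k = 1,
                 candidate_pool = 2)), 2L)
  expect_error(select_first_gene(ds, selection_config(k = 1,
                 candidate_pool = integer(0))), "empty")
})

test_that("a greedy step finds the separating candidate and matches a fresh argmax", {
  set.seed(6)
  x <- cbind(g1 = rnorm(12),                                  # noise
             g2 = c(rep(0, 6), rep(10, 6)) + rnorm(12, 0.1),  # separator
             g3 = rnorm(12))
  rownames(x) <- paste0("s", 1:12)
  ds <- labeled_dataset(x, rep(c("A", "B"), each = 6))
  cfg <- selection_config(k = 2)
  st <- squared_distances(ds$x, 1L)     # noise gene first, by fiat
  step <- greedy_step(ds, 1L, st, cfg)
  expect_equal(step$gene, 2L)
  expect_gt(step$score, wlms_for_subset(ds, 1L, cfg$k))

  # equals from-scratch argmax on random datasets
  set.seed(7)
  for (r in 1:10) {
    ds <- tiny_dataset(seed = 100 + r, m_per_class = 6, n_genes = 6)
    cur <- sample(6, 2)
    st <- squared_distances(ds$x, cur)
    step <- greedy_step(ds, cur, st, selection_config(k = 2))
    cands <- setdiff(1:6, cur)
    sc <- vapply(cands, function(g)
      wlms_for_subset(ds, c(cur, g), 2), numeric(1))
    expect_equal(step$gene, cands[which.max(sc)])
    expect_equal(step$score, max(sc), tolerance = 1e-12)
  }

  # exhausted pool signals NULL
  ds <- separating_dataset()
  st <- squared_distances(ds$x, 1:2)
  expect_null(greedy_step(ds, 1:2, st, selection_config(k = 1)))
})

test_that("stopping rules: theta rejects the sub-threshold candidate, lambda caps", {
  ds <- separating_dataset()
  one <- wlmgs_select(ds, selection_config(k = 1, theta = Inf))
  expect_equal(length(one$genes), 1L)
  expect_equal(one$stopped_by, "theta")
  expect_equal(one$increments, one$scores)

  capped <- wlmgs_select(ds, selection_config(k = 1, theta = 0, lambda_max = 2))
  expect_equal(length(capped$genes), 2L)
  expect_equal(capped$stopped_by, "lambda")

  # three perfectly separating genes keep WLM^s pinned at 2, so every
  # increment is exactly 0: theta = 0 blocks only strictly negative gains
  # and the cap binds
  set.seed(12)
  xsep <- matrix(rep(c(0, 100), each = 5), 10, 3) + rnorm(30, sd = 0.01)
  dimnames(xsep) <- list(paste0("s", 1:10), paste0("g", 1:3))
  dsep <- labeled_dataset(xsep, rep(c("A", "B"), each = 5))
  pool3 <- wlmgs_select(dsep, selection_config(k = 2, theta = 0,
                                               lambda_max = 3))
  expect_equal(length(pool3$genes), 3L)
  expect_equal(pool3$stopped_by, "lambda")

  all5 <- wlmgs_select(tiny_dataset(1, 6, 5),
                       selection_config(k = 2, stop_rule = "cap-only",
                                        lambda_max = 5))
  expect_equal(sort(all5$genes), 1:5)
  expect_equal(all5$stopped_by, "lambda")
})

test_that("selection results are deterministic and trajectory-consistent", {
  g <- generate_dataset(synthetic_spec(seed = 3))
  ds <- labeled_dataset(zscore_normalize(g$dataset$x), g$dataset$labels)
  cfg <- selection_config()
  a <- wlmgs_select(ds, cfg)
  b <- wlmgs_select(ds, cfg)
  expect_same_selection(a, b)
  expect_equal(length(a$scores), length(a$genes))
  expect_equal(a$increments[-1], diff(a$scores))
  # re-scoring every prefix from scratch reproduces the trajectory
  for (i in seq_along(a$genes))
    expect_equal(wlms_for_subset(ds, a$genes[seq_len(i)], cfg$k),
                 a$scores[i], tolerance = 1e-10)
})

test_that("pure-noise data stops well short of the gene cap", {
  sizes <- vapply(1:20, function(s) {
    g <- generate_dataset(synthetic_spec(
      samples_per_class = c(20, 20), n_informative = 0, n_noise = 100,
      seed = s))
    ds <- labeled_dataset(zscore_normalize(g$dataset$x), g$dataset$labels)
    length(wlmgs_select(ds, selection_config())$genes)
  }, numeric(1))
  expect_lt(median(sizes), 15)
})

test_that("informative genes dominate the selection on the default design", {
  rec <- vapply(1:20, function(s) {
    g <- generate_dataset(synthetic_spec(seed = s))
    ds <- labeled_dataset(zscore_normalize(g$dataset$x), g$dataset$labels)
    res <- wlmgs_select(ds, selection_config())
    # median selection rank of informative vs noise genes; unselected genes
    # share the mid-rank of the remainder
    n <- ncol(ds$x)
    rank_of <- rep(length(res$genes) + (n - length(res$genes) + 1) / 2, n)
    rank_of[res$genes] <- seq_along(res$genes)
    c(rec = sum(res$genes %in% g$truth$informative),
      med_inf = median(rank_of[g$truth$informative]),
      med_noise = median(rank_of[g$truth$noise]))
  }, numeric(3))
  # majority of seeds recover at least 4 of the 5 informative genes
  expect_gt(mean(rec["rec", ] >= 4), 0.5)
  # informative genes rank above noise genes in every seed
  expect_true(all(rec["med_inf", ] < rec["med_noise", ]))
})

test_that("raising the effect size never lowers median recovery (0.5 to 2 SD)", {
  med <- vapply(c(0.5, 1, 1.5, 2), function(e) {
    median(vapply(1:20, function(s) {
      g <- generate_dataset(synthetic_spec(effect_size = e, seed = s))
      ds <- labeled_dataset(zscore_normalize(g$dataset$x), g$dataset$labels)
      sum(wlmgs_select(ds, selection_config())$genes %in% g$truth$informative)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
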