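test_that("community weights reproduce the hand-enumerated path fixture", {
  fx <- fixture_graph("path-4")
  cw <- community_weights(fx$graph, fx$labels)
  for (cl in c("A", "B")) {
    row <- cw[cw$class == cl, ]
    expect_equal(row$w, exp(-2))
    expect_equal(row$w_out, exp(-1))
    expect_equal(row$W, exp(-2) + exp(-1))
    expect_equal(row$s, 2 * exp(-2) + exp(-1))
    expect_equal(row$m_edges, 1); expect_equal(row$b_edges, 1)
    expect_equal(row$M, 2); expect_equal(row$d, 3)
  }
  # no between-class edges: w_out = 0 and W = w per class
  ip <- fixture_graph("isolated-pairs")
  cwi <- community_weights(ip$graph, ip$labels)
  expect_equal(cwi$w_out, c(0, 0))
  expect_equal(cwi$W, cwi$w)
})

test_that("community-weight identities hold on random labelled graphs", {
  for (r in 1:50) {
    fx <- fixture_graph("random", m = 5 + (r %% 11), C = 2 + (r %% 3),
                        seed = 100 + r)
    cw <- community_weights(fx$graph, fx$labels)
    expect_equal(cw$W, cw$w + cw$w_out)
    expect_equal(cw$s, 2 * cw$w + cw$w_out)
    # sum_k s_k = 2 * total edge weight = sum of the full affinity matrix
    expect_equal(sum(cw$s), sum(fx$graph$A))
    # per-node strength oracle
    strength <- rowSums(fx$graph$A)
    for (i in seq_len(nrow(cw))) {
      idx <- which(as.character(fx$labels) == cw$class[i])
      expect_equal(cw$s[i], sum(strength[idx]))
    }
    # cross-library check: igraph's strengths aggregate to the same s_k
    if (r <= 10) {
      gi <- igraph::graph_from_adjacency_matrix(fx$graph$A,
              mode = "undirected", weighted = TRUE)
      st_ig <- igraph::strength(gi)
      for (i in seq_len(nrow(cw)))
        expect_equal(cw$s[i],
          sum(st_ig[as.character(fx$labels) == cw$class[i]]))
    }
    # boundary weight double-counts globally: sum_k w_out = 2 * between-class weight
    between <- 0
    A <- fx$graph$A; lab <- as.character(fx$labels)
    for (i in seq_len(nrow(A) - 1)) for (j in (i + 1):nrow(A))
      if (A[i, j] > 0 && lab[i] != lab[j]) between <- between + A[i, j]
    expect_equal(sum(cw$w_out), 2 * between)
  }
})

test_that("LM, WLM and WLM^s agree with the edge-enumeration oracle", {
  max_d <- 0
  for (r in 1:50) {
    fx <- fixture_graph("random", m = 5 + (r %% 11), C = 2 + (r %% 3),
                        seed = r)
    oc <- oracle_scores(fx$graph$A, fx$labels)
    max_d <- max(max_d,
                 abs(local_modularity(fx$graph, fx$labels)$value - oc$lm),
                 abs(weight_local_modularity(fx$graph, fx$labels)$value - oc$wlm),
                 abs(wlm_s(fx$graph, fx$labels)$value - oc$wlms))
  }
  expect_lt(max_d, 1e-12)
})

test_that("analytic limits of the score family hold", {
  # two isolated triangles, one class each: LM term 3/3 - (6/6)^2 = 0
  tt <- fixture_graph("two-triangles")
  expect_equal(local_modularity(tt$graph, tt$labels)$value, 0)
  expect_equal(wlm_s(tt$graph, tt$labels)$value, 2)

  # empty graph contributes nothing
  empty <- structure(list(A = matrix(0, 4, 4), k = NA, subset = integer(0)),
                     class = "wsg")
  expect_equal(local_modularity(empty, c("A", "A", "B", "B"))$value, 0)
  expect_equal(wlm_s(empty, c("A", "A", "B", "B"))$value, 0)

  # no boundary edges forces WLM = 0 (s_k = 2 w_k) and WLM^s = C
  ip <- fixture_graph("isolated-pairs")
  expect_equal(weight_local_modularity(ip$graph, ip$labels)$value, 0)
  expect_equal(wlm_s(ip$graph, ip$labels)$value, 2)

  # only between-class edges: all numerators vanish
  bip <- structure(list(A = rbind(c(0, 0, 0.5, 0.2), c(0, 0, 0.1, 0.7),
                                  c(0.5, 0.1, 0, 0), c(0.2, 0.7, 0, 0)),
                        k = NA, subset = integer(0)), class = "wsg")
  expect_equal(wlm_s(bip, c("A", "A", "B", "B"))$value, 0)

  # path fixture values
  fx <- fixture_graph("path-4")
  expect_equal(wlm_s(fx$graph, fx$labels)$value,
               2 * exp(-2) / (exp(-2) + exp(-1)))
  expect_equal(round(wlm_s(fx$graph, fx$labels)$value, 4), 0.5379)
  expect_equal(weight_local_modularity(fx$graph, fx$labels)$value,
               2 * (exp(-2) / (exp(-2) + exp(-1)) -
                    ((2 * exp(-2) + exp(-1)) / (2 * (exp(-2) + exp(-1))))^2))
})

test_that("WLM^s is bounded by the class count and responds to boundary scaling", {
  for (r in 1:20) {
    C <- 2 + (r %% 3)
    fx <- fixture_graph("random", m = 8 + (r %% 7), C = C, seed = 500 + r)
    v <- wlm_s(fx$graph, fx$labels)$value
    expect_gte(v, 0); expect_lte(v, C)

    # shrink between-class weights by t in (0,1): score strictly increases
    A <- fx$graph$A; lab <- as.character(fx$labels)
    boundary <- outer(lab, lab, "!=") & A > 0
    internal <- outer(lab, lab, "==") & A > 0
    if (any(boundary) && any(internal)) {
      A2 <- A; A2[boundary] <- 0.5 * A2[boundary]
      g2 <- structure(list(A = A2, k = NA, subset = integer(0)), class = "wsg")
      expect_gt(wlm_s(g2, fx$labels)$value, v)
    }
  }
})

test_that("subset scoring composes graph construction and WLM^s", {
  # perfectly separated 1-D classes: no between-class k-NN edges
  x <- as_expression_matrix(matrix(c(0, 0.1, 10, 10.1), ncol = 1,
         dimnames = list(paste0("s", 1:4), "g1")))
  ds <- labeled_dataset(x, c("A", "A", "B", "B"))
  expect_equal(wlms_for_subset(ds, 1, k = 1), 2)

  # labels shuffled so each class mixes both clusters: strictly lower
  ds_mix <- labeled_dataset(x, c("A", "B", "A", "B"))
  expect_lt(wlms_for_subset(ds_mix, 1, k = 1), 2)

  set.seed(77)
  for (r in 1:20) {
    m <- sample(8:14, 1); n <- sample(2:5, 1)
    xr <- as_expression_matrix(matrix(rnorm(m * n), m,
            dimnames = list(paste0("s", 1:m), paste0("g", 1:n))))
    ds <- labeled_dataset(xr, sample(c("A", "B"), m, replace = TRUE) |>
                            (\(l) {l[1:2] <- c("A", "B"); l})())
    sub <- sample(n, sample(n, 1))
    k <- sample(1:3, 1)
    composed <- wlm_s(build_wsg(ds$x, sub, k), ds$labels)$value
    expect_equal(wlms_for_subset(ds, sub, k), composed, tolerance = 1e-12)
  }
})
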