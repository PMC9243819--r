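test_that("degenerate overlap targets collapse the conditional layer", {
  # v = r = 1: layer 2 duplicates layer 1 exactly
  m <- generate_er_pair(50, r = 1, v = 1, seed = 1)
  expect_equal(m$layers[[2]], m$layers[[1]])

  # v = 0, r = 1: edge-disjoint layers
  m <- generate_er_pair(50, r = 1, v = 0, seed = 2)
  k1 <- pair_key(m$layers[[1]][, 1], m$layers[[1]][, 2], 50)
  k2 <- pair_key(m$layers[[2]][, 1], m$layers[[2]][, 2], 50)
  expect_length(intersect(k1, k2), 0)
})

test_that("infeasible pair specifications are rejected", {
  expect_error(generate_er_pair(100, r = 0.3, v = 0.5, seed = 1), "\\[0, r\\]")
  expect_error(generate_er_pair(5, r = 0.5, v = 0.2, seed = 1), "exceed 6")
})

test_that("pair generator recovers the target moments", {
  # sample means of <k1>, r, v over replicates vs their design values,
  # within 3 standard errors (moderate size here; the full-scale check
  # lives in the acceptance suite)
  reps <- 60
  stats <- t(vapply(seq_len(reps), function(k) {
    m <- generate_er_pair(400, r = 0.5, v = 0.2, seed = case_seed(11, k))
    ch <- characterize_multiplex(m)
    c(ch$mean_degrees[1], ch$r, ch$v)
  }, numeric(3)))
  for (col_target in list(c(1, 5), c(2, 0.5), c(3, 0.2))) {
    x <- stats[, col_target[1]]
    se <- sd(x) / sqrt(reps)
    expect_lt(abs(mean(x) - col_target[2]), 3 * se + 1e-12)
  }
})

test_that("degree-sequence generator follows the Bernoulli law", {
  # only the two positive-degree nodes can link
  d <- rep(0, 6); d[2] <- 1.4; d[5] <- 0.9
  m <- generate_from_degree_sequences(d, d, seed = 3)
  for (e in m$layers) {
    if (nrow(e) > 0) expect_true(all(e[, 1] == 2 & e[, 2] == 5))
  }

  # uniform degrees: E<k> = N k^2 / (N k - 1), close to k
  n <- 120; k <- 4
  kb <- vapply(1:40, function(s) {
    m <- generate_from_degree_sequences(rep(k, n), rep(k, n),
                                        seed = case_seed(5, s))
    characterize_multiplex(m)$mean_degrees
  }, numeric(2))
  expected <- n * k^2 / (n * k - 1)
  se <- sd(kb) / sqrt(length(kb))
  expect_lt(abs(mean(kb) - expected), 3 * se + 1e-12)

  # per-node degree recovery
  set.seed(9)
  d1 <- runif(80, 1, 6)
  deg <- rowMeans(vapply(1:50, function(s) {
    m <- generate_from_degree_sequences(d1, d1, seed = case_seed(77, s))
    edge_degrees(m$layers[[1]], 80)
  }, numeric(80)))
  expect_gt(cor(deg, d1), 0.95)

  expect_error(generate_from_degree_sequences(c(50, 50, 1), c(1, 1, 1)),
               "exceeds 1")
})

test_that("degree-sequence pairs hit the cosine target", {
  for (target in c(0.15, 0.5, 0.9)) {
    ds <- make_degree_sequences(300, target, seed = round(100 * target))
    expect_true(all(ds$d1 > 0) && all(ds$d2 > 0))
    expect_lt(abs(ds$cosine - target), 0.02 + 1e-12)
    recomputed <- sum(ds$d1 * ds$d2) / sqrt(sum(ds$d1^2) * sum(ds$d2^2))
    expect_equal(ds$cosine, recomputed)
  }
  expect_error(make_degree_sequences(100, 1.2), "\\(0, 1\\)")
})

test_that("vertex sampling observes the induced subgraph in all layers", {
  m <- generate_er_pair(100, r = 0.8, v = 0.2, seed = 4)
  agg <- aggregate_or(m)

  expect_equal(nrow(sample_observations_vertex(m, 0, seed = 1)$entries), 0)

  g1 <- sample_observations_vertex(m, 1, seed = 1)
  expect_equal(nrow(g1$entries), 2 * agg$n_edges)
  expect_equal(g1$c, 1)

  # c = 0.25 at N = 100 samples 50 nodes; entries come in full-layer groups
  g <- sample_observations_vertex(m, 0.25, seed = 2)
  expect_lte(length(unique(c(g$entries$i, g$entries$j))), 50)
  expect_equal(nrow(g$entries) %% m$n_layers, 0)
  # observed values match the ground truth
  for (a in 1:2) {
    e <- g$entries[g$entries$layer == a, ]
    truth_keys <- pair_key(m$layers[[a]][, 1], m$layers[[a]][, 2], 100)
    expect_equal(e$value,
                 as.integer(pair_key(e$i, e$j, 100) %in% truth_keys))
  }
  # realized fraction concentrates near the nominal one
  cs <- vapply(1:30, function(s) {
    sample_observations_vertex(m, 0.25, seed = case_seed(3, s))$c
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.25), 0.05)
})

test_that("per-layer budget sampling respects the layer fractions", {
  m <- generate_er_pair(100, r = 0.8, v = 0.2, seed = 4)
  g <- sample_observations_budget(m, 0, 1, seed = 5)
  expect_equal(unique(g$entries$layer), 2L)
  expect_equal(g$c_layer[1], 0)
  expect_equal(g$c_layer[2], 1)

  g2 <- sample_observations_budget(m, 0.4, 0.2, seed = 6)
  expect_gt(g2$c_layer[1], g2$c_layer[2])

  # shared-node mode nests the layer-2 set in the layer-1 set
  g3 <- sample_observations_budget(m, 0.6, 0.2, seed = 7,
                                   shared_nodes = TRUE)
  n1 <- unique(c(g3$entries$i[g3$entries$layer == 1],
                 g3$entries$j[g3$entries$layer == 1]))
  n2 <- unique(c(g3$entries$i[g3$entries$layer == 2],
                 g3$entries$j[g3$entries$layer == 2]))
  expect_true(all(n2 %in% n1))
})
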