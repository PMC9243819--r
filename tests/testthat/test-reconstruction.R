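test_that("configuration-model edge priors follow d_i d_j / (S - 1)", {
  p <- degree_params(cbind(c(0, 1, 2, 3)))
  expect_equal(edge_prior_prob(p, 1, 2, 1), 0)          # zero endpoint
  p2 <- degree_params(cbind(c(1, 1)))
  expect_equal(edge_prior_prob(p2, 1, 2, 1), 1)         # capped at 1
  p3 <- degree_params(cbind(c(2, 3, 20)))
  expect_equal(edge_prior_prob(p3, 1, 2, 1), 6 / 24)    # 2*3/(25-1)
  expect_error(edge_prior_prob(p3, 1, 1, 1), "self-pairs")
})

test_that("E-step posteriors honor the OR constraint and observations", {
  one_edge <- aggregate_topology(cbind(1, 2), 2)
  # parameters giving pi exactly 0.5 in both layers:
  # d = (0.4, 3) has d_i d_j / (S - 1) = 1.2 / 2.4 = 1/2
  p_half <- degree_params(cbind(c(0.4, 3), c(0.4, 3)))

  g_none <- observation_set(NULL, one_edge, 2)
  post <- em_e_step(one_edge, g_none, p_half)
  expect_equal(as.vector(post$state_probs), rep(1 / 3, 3))
  expect_equal(as.vector(post$marginals), c(2 / 3, 2 / 3))

  # observing layer 1 present removes the OR coupling
  g1 <- observation_set(data.frame(i = 1, j = 2, layer = 1, value = 1),
                        one_edge, 2)
  post <- em_e_step(one_edge, g1, p_half)
  expect_equal(post$marginals[1, 1], 1)
  expect_equal(post$marginals[1, 2], 0.5)

  # observing layer 1 absent forces layer 2
  g0 <- observation_set(data.frame(i = 1, j = 2, layer = 1, value = 0),
                        one_edge, 2)
  post <- em_e_step(one_edge, g0, p_half)
  expect_equal(post$marginals[1, 1], 0)
  expect_equal(post$marginals[1, 2], 1)

  # zero prior mass everywhere: uniform over consistent states
  p_zero <- degree_params(cbind(c(0, 0), c(0, 0)))
  post <- em_e_step(one_edge, g_none, p_zero)
  expect_equal(as.vector(post$state_probs), rep(1 / 3, 3))
  expect_equal(post$n_degenerate, 1)
})

test_that("M-step accumulates expected degrees", {
  m <- toy_two_layer()
  post <- em_e_step(aggregate_or(m), full_observation(m),
                    degree_params(matrix(1, 3, 2)))
  fitted <- em_m_step(post)
  expect_equal(fitted$d[, 1], edge_degrees(m$layers[[1]], 3))
  expect_equal(fitted$d[, 2], edge_degrees(m$layers[[2]], 3))

  # single unobserved edge with Q = 2/3 gives both endpoints d = 2/3
  one_edge <- aggregate_topology(cbind(1, 2), 2)
  post <- em_e_step(one_edge, observation_set(NULL, one_edge, 2),
                    degree_params(cbind(c(0.4, 3), c(0.4, 3))))
  fitted <- em_m_step(post)
  expect_equal(fitted$d, matrix(2 / 3, 2, 2))

  # star on 4 nodes with reliability 1/2 per spoke: center degree 1.5
  star <- aggregate_topology(rbind(c(1, 2), c(1, 3), c(1, 4)), 4)
  post <- em_e_step(star, observation_set(NULL, star, 2),
                    degree_params(matrix(1, 4, 2)))
  post$marginals[] <- 0.5
  fitted <- em_m_step(post)
  expect_equal(fitted$d[1, ], c(1.5, 1.5))
})

test_that("E-step equals the brute-force enumeration oracle", {
  # the per-edge likelihood factorizes, so the equivalence must be exact
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:7, 1)
    m <- random_multiplex(n, 0.3, 0.3)
    agg <- aggregate_or(m)
    if (agg$n_edges == 0 || agg$n_edges > 6) next
    d <- matrix(runif(2 * n, 0.2, 2), n, 2)
    params <- degree_params(d)
    # observe a random subset of entries
    fo <- full_observation(m)$entries
    take <- runif(nrow(fo)) < 0.4
    g <- observation_set(fo[take, ], agg, 2)
    fast <- em_e_step(agg, g, params)
    slow <- enumerate_posterior(agg, g, params)
    expect_equal(fast$marginals, slow$marginals, tolerance = 1e-10)
  }
})

test_that("oracle puts point mass on fully observed structures", {
  m <- toy_two_layer()
  agg <- aggregate_or(m)
  params <- degree_params(matrix(0.8, 3, 2))
  slow <- enumerate_posterior(agg, full_observation(m), params)
  expected <- cbind(c(1, 0), c(0, 1))  # edge 1-2 in layer 1, 2-3 in layer 2
  expect_equal(slow$marginals, expected)
  expect_error(
    enumerate_posterior(aggregate_topology(t(combn(30, 2)), 30),
                        observation_set(NULL, aggregate_topology(t(combn(30, 2)), 30), 2),
                        degree_params(matrix(1, 30, 2))),
    "enumeration guard")
})

test_that("EM lower bound is monotone and c = 1 recovers the network", {
  set.seed(5)
  m <- generate_er_pair(60, r = 0.6, v = 0.2, seed = 8)
  agg <- aggregate_or(m)

  g <- sample_observations_budget(m, 0.4, 0.4, seed = 9)
  fit <- reconstruct_em(agg, g, 2, em_control(restarts = 2, max_iter = 80,
                                              tol = 1e-7, seed = 10))
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_equal(fit$best_restart, which.max(fit$logJ_restarts))

  # complete observation pins every reliability to the truth
  fit1 <- reconstruct_em(agg, full_observation(m), 2,
                         em_control(restarts = 1, seed = 11))
  expect_true(all(fit1$posterior$marginals %in% c(0, 1)))
  rec <- binarize_reconstruction(fit1$posterior)
  expect_equal(rec$layers, m$layers)
})

test_that("a single layer forces every aggregate edge present", {
  m <- multiplex_network(list(rbind(c(1, 2), c(2, 3), c(3, 4))), 4)
  agg <- aggregate_or(m)
  fit <- reconstruct_em(agg, observation_set(NULL, agg, 1), 1,
                        em_control(restarts = 1, max_iter = 20, seed = 1))
  expect_equal(as.vector(fit$posterior$marginals), rep(1, 3))
})

test_that("binarization thresholds reliabilities", {
  one_edge <- aggregate_topology(cbind(1, 2), 2)
  post <- em_e_step(one_edge, observation_set(NULL, one_edge, 2),
                    degree_params(cbind(c(1, 1), c(1, 1))))
  post$marginals <- matrix(c(0.6, 0.4), 1, 2)
  rec <- binarize_reconstruction(post, q = 0.5)
  expect_equal(nrow(rec$layers[[1]]), 1)
  expect_equal(nrow(rec$layers[[2]]), 0)
})

test_that("expected degree distribution matches closed forms", {
  # single edge on 2 nodes with Q1 = 2/3: P(k=1) = 2/3 per endpoint
  one_edge <- aggregate_topology(cbind(1, 2), 2)
  post <- em_e_step(one_edge, observation_set(NULL, one_edge, 2),
                    degree_params(cbind(c(0.4, 3), c(0.4, 3))))
  dist <- expected_degree_distribution(post, 1, samples = 4000, seed = 2)
  expect_equal(dist$prob[dist$degree == 1], 2 / 3, tolerance = 0.05)
  expect_equal(dist$prob[dist$degree == 0], 1 / 3, tolerance = 0.1)

  # degenerate posterior: exact histogram, samples ignored
  m <- toy_two_layer()
  fit <- reconstruct_em(aggregate_or(m), full_observation(m), 2,
                        em_control(restarts = 1, seed = 1))
  dist <- expected_degree_distribution(fit$posterior, 1, samples = 1)
  expect_equal(dist$prob, c(1 / 3, 2 / 3))  # degrees of layer {1-2}: 0 once, 1 twice
})

test_that("fitted degree parameters track the truth at moderate c", {
  cors <- vapply(1:8, function(s) {
    set.seed(case_seed(21, s))
    d1 <- runif(150, 1, 7)
    d2 <- runif(150, 1, 7)
    m <- generate_from_degree_sequences(d1, d2, seed = case_seed(22, s))
    agg <- aggregate_or(m)
    g <- sample_observations_budget(m, 0.6, 0.6, seed = case_seed(23, s))
    fit <- reconstruct_em(agg, g, 2, em_control(restarts = 1, max_iter = 40,
                                                tol = 1e-5,
                                                seed = case_seed(24, s)))
    true_d <- cbind(edge_degrees(m$layers[[1]], 150),
                    edge_degrees(m$layers[[2]], 150))
    (cor(fit$params$d[, 1], true_d[, 1]) +
       cor(fit$params$d[, 2], true_d[, 2])) / 2
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})
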