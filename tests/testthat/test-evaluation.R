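# Build a posterior/truth/test-set triple with prescribed reliabilities and
# truth labels: items are the layer-1 memberships of a chain's edges, layer 2
# carries every edge so only layer 1 is under test.
scored_instance <- function(scores, labels) {
  n_items <- length(scores)
  n <- n_items + 1
  edges <- cbind(seq_len(n_items), seq_len(n_items) + 1)
  agg <- aggregate_topology(edges, n)
  post <- structure(
    list(edges = agg$edges, n_nodes = n, n_layers = 2,
         states = membership_states_for_tests(),
         state_probs = NULL,
         marginals = cbind(scores, 1),   # layer 2 carries every edge
         observed = matrix(NA_integer_, n_items, 2)),
    class = "link_posterior")
  truth <- multiplex_network(
    list(edges[labels == 1, , drop = FALSE], edges), n)
  items <- data.frame(i = edges[, 1], j = edges[, 2], layer = 1)
  ts <- structure(list(items = items, n_items = n_items), class = "test_set")
  list(post = post, truth = truth, ts = ts)
}

membership_states_for_tests <- function() {
  rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
}

# Exhaustive pairwise AUC oracle with ties counting one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("confusion counts apply the half-contribution rule", {
  x <- scored_instance(c(0.9, 0.3), c(1, 0))
  cc <- confusion_counts(x$post, x$truth, x$ts, q = 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 1, fn = 0))

  # hand enumeration with ties at the threshold
  x <- scored_instance(c(0.9, 0.5, 0.3, 0.5), c(1, 1, 0, 0))
  cc <- confusion_counts(x$post, x$truth, x$ts, q = 0.5)
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]),
               c(tp = 1.5, fn = 0.5, tn = 1.5, fp = 0.5))
  sm <- summary_metrics(cc)
  expect_equal(sm$accuracy, 0.75)
  expect_equal(sm$precision, 0.75)
  expect_equal(sm$recall, 0.75)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, x$ts$n_items)

  # perfect reconstruction
  x <- scored_instance(c(1, 0, 1), c(1, 0, 1))
  expect_equal(summary_metrics(confusion_counts(x$post, x$truth, x$ts))$accuracy, 1)
})

test_that("undefined ratios are NA flags, not zeros", {
  x <- scored_instance(c(0.9, 0.8), c(0, 0))   # all-negative truth, all-positive calls
  sm <- summary_metrics(confusion_counts(x$post, x$truth, x$ts))
  expect_equal(sm$precision, 0)
  expect_true(is.na(sm$recall))   # TP + FN = 0
  expect_true(is.na(sm$mcc))
  x2 <- scored_instance(c(1, 0, 1), c(1, 0, 1))   # FP = FN = 0
  sm2 <- summary_metrics(confusion_counts(x2$post, x2$truth, x2$ts))
  expect_equal(sm2$precision, 1)
  expect_equal(sm2$recall, 1)
  expect_equal(sm2$mcc, 1)
})

test_that("AUC follows the rank formulation with half ties", {
  x <- scored_instance(c(0.9, 0.7, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(rank_metrics(x$post, x$truth, x$ts)$auc, 1)

  x <- scored_instance(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(rank_metrics(x$post, x$truth, x$ts)$auc, 0.5)

  # exhaustive pair enumeration is authoritative: one concordant pair,
  # one discordant pair out of 2 positives x 1 negative
  sc <- c(0.9, 0.8, 0.4); lb <- c(1, 0, 1)
  x <- scored_instance(sc, lb)
  expect_equal(rank_metrics(x$post, x$truth, x$ts)$auc, auc_oracle(sc, lb))
  expect_equal(auc_oracle(sc, lb), 0.5)

  expect_error(rank_metrics(scored_instance(c(0.2, 0.3), c(1, 1))$post,
                            scored_instance(c(0.2, 0.3), c(1, 1))$truth,
                            scored_instance(c(0.2, 0.3), c(1, 1))$ts),
               "negative")
})

test_that("rank metrics agree with the pairwise oracle and pROC on random inputs", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    sc <- round(runif(n), sample(c(1, 2, 7), 1))  # rounding makes ties likely
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    x <- scored_instance(sc, lb)
    rm <- rank_metrics(x$post, x$truth, x$ts)
    expect_equal(rm$auc, auc_oracle(sc, lb))
    proc_auc <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                               direction = "<")))
    expect_equal(rm$auc, proc_auc)
    # permutation invariance
    perm <- sample(n)
    x2 <- scored_instance(sc[perm], lb[perm])
    rm2 <- rank_metrics(x2$post, x2$truth, x2$ts)
    expect_equal(rm2$auc, rm$auc)
    expect_equal(rm2$auprc, rm$auprc)
  }
})

test_that("reliabilities independent of the truth give AUC near one half", {
  set.seed(88)
  aucs <- replicate(60, {
    sc <- runif(30)
    lb <- c(1, 0, rbinom(28, 1, 0.5))  # both classes guaranteed
    x <- scored_instance(sc, lb)
    rank_metrics(x$post, x$truth, x$ts)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("the full report combines threshold and ranking metrics", {
  x <- scored_instance(c(0.9, 0.6, 0.2, 0.4), c(1, 1, 0, 0))
  rep <- evaluate_reconstruction(x$post, x$truth, x$ts)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$auprc, 1)
})
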