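# Small builders shared across the test files.

# Two-layer toy: layer 1 = {1-2}, layer 2 = {2-3}.
toy_two_layer <- function() {
  multiplex_network(list(cbind(1, 2), cbind(2, 3)), n_nodes = 3)
}

# A random two-layer multiplex on n nodes with independent ER layers.
random_multiplex <- function(n, p1 = 0.3, p2 = 0.3) {
  pairs <- t(combn(n, 2))
  multiplex_network(
    list(pairs[runif(nrow(pairs)) < p1, , drop = FALSE],
         pairs[runif(nrow(pairs)) < p2, , drop = FALSE]),
    n_nodes = n
  )
}

# Full observation of every entry of a multiplex network.
full_observation <- function(m) {
  agg <- aggregate_or(m)
  entries <- do.call(rbind, lapply(seq_len(m$n_layers), function(a) {
    keys <- pair_key(m$layers[[a]][, 1], m$layers[[a]][, 2], m$n_nodes)
    val <- pair_key(agg$edges[, 1], agg$edges[, 2], m$n_nodes) %in% keys
    data.frame(i = agg$edges[, 1], j = agg$edges[, 2], layer = a,
               value = as.integer(val))
  }))
  observation_set(entries, agg, m$n_layers)
}

empty_observation <- function(m) {
  observation_set(NULL, aggregate_or(m), m$n_layers)
}

# Deterministic sub-seed derivation for loops over cases.
case_seed <- function(base, k) (base * 7919L + k * 104729L) %% 2100000000L
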