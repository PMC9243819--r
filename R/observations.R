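#' Construct a partial-observation set
#'
#' A partial observation records, for some aggregate edges `(i, j)` and layer
#' indices `a`, whether the link is present in that layer (`value` 0 or 1).
#' Observations are only defined over aggregate edges: the OR constraint makes
#' absence in one layer informative about the remaining layers.
#'
#' @param entries data frame (or matrix) with columns `i`, `j`, `layer`,
#'   `value`; both pair orientations accepted.
#' @param aggregate the companion [aggregate_topology].
#' @param n_layers number of layers `L`.
#' @return an `observation_set` with fields `entries` (canonical, `i < j`,
#'   sorted by pair then layer), `n_layers`, `c` (overall observed fraction
#'   `card(Gamma) / (L |A|)`) and `c_layer` (per-layer fractions).
#' @export
observation_set <- function(entries, aggregate, n_layers) {
  stopifnot(inherits(aggregate, "aggregate_topology"))
  n_layers <- as.integer(n_layers)
  if (is.null(entries) || NROW(entries) == 0) {
    entries <- data.frame(i = integer(0), j = integer(0),
                          layer = integer(0), value = integer(0))
  }
  entries <- as.data.frame(entries)[, 1:4]
  names(entries) <- c("i", "j", "layer", "value")
  ii <- pmin(entries$i, entries$j)
  jj <- pmax(entries$i, entries$j)
  entries$i <- as.integer(ii)
  entries$j <- as.integer(jj)
  entries$layer <- as.integer(entries$layer)
  entries$value <- as.integer(entries$value)
  if (any(entries$layer < 1L | entries$layer > n_layers)) {
    stop("observation layer index outside 1..L", call. = FALSE)
  }
  if (!all(entries$value %in% c(0L, 1L))) {
    stop("observation values must be 0 or 1", call. = FALSE)
  }
  n <- aggregate$n_nodes
  agg_keys <- pair_key(aggregate$edges[, 1], aggregate$edges[, 2], n)
  obs_keys <- pair_key(entries$i, entries$j, n)
  if (!all(obs_keys %in% agg_keys)) {
    stop("observations reference node pairs absent from the aggregate topology",
         call. = FALSE)
  }
  full_key <- obs_keys * (n_layers + 1) + entries$layer
  if (anyDuplicated(full_key)) {
    stop("duplicate (i, j, layer) observations", call. = FALSE)
  }
  # OR violation: a fully observed pair with all layer values 0 contradicts
  # the aggregate edge it sits on.
  zero_by_pair <- tapply(entries$value, obs_keys, function(v) {
    length(v) == n_layers && all(v == 0L)
  })
  if (any(unlist(zero_by_pair))) {
    stop("OR constraint violated: an aggregate edge is observed absent in all layers",
         call. = FALSE)
  }
  ord <- order(entries$i, entries$j, entries$layer)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  m <- aggregate$n_edges
  c_all <- if (m > 0) nrow(entries) / (n_layers * m) else 0
  c_layer <- if (m > 0) tabulate(entries$layer, nbins = n_layers) / m else rep(0, n_layers)
  structure(
    list(entries = entries, n_layers = n_layers, c = c_all, c_layer = c_layer),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d entries, c = %.4f (per layer: %s)\n",
              nrow(x$entries), x$c,
              paste(sprintf("%.4f", x$c_layer), collapse = ", ")))
  invisible(x)
}

#' Overall observed fraction
#'
#' `c = card(Gamma) / (L |A|)`: the share of the `L |A|` potential layer
#' memberships of aggregate edges that have been observed.
#'
#' @param obs an [observation_set].
#' @param aggregate the companion [aggregate_topology].
#' @param n_layers number of layers.
#' @return the fraction in `[0, 1]`.
#' @export
observed_fraction <- function(obs, aggregate, n_layers) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(aggregate, "aggregate_topology"))
  if (aggregate$n_edges == 0) {
    stop("observed fraction undefined: the aggregate topology has no edges",
         call. = FALSE)
  }
  nrow(obs$entries) / (n_layers * aggregate$n_edges)
}

#' Testing set of unobserved potential links
#'
#' All `(i, j, layer)` triples with an aggregate edge between `i` and `j`
#' that are not in the observation set; the reconstruction is evaluated on
#' exactly these entries.
#'
#' @param aggregate an [aggregate_topology].
#' @param obs an [observation_set] consistent with `aggregate`.
#' @param n_layers number of layers `L`.
#' @return a `test_set` with fields `items` (data frame `i`, `j`, `layer`)
#'   and `n_items` (`= L |A| - card(Gamma)`).
#' @export
build_test_set <- function(aggregate, obs, n_layers) {
  stopifnot(inherits(aggregate, "aggregate_topology"),
            inherits(obs, "observation_set"))
  n <- aggregate$n_nodes
  m <- aggregate$n_edges
  items <- data.frame(
    i = rep(aggregate$edges[, 1], each = n_layers),
    j = rep(aggregate$edges[, 2], each = n_layers),
    layer = rep(seq_len(n_layers), times = m)
  )
  if (nrow(obs$entries) > 0) {
    obs_key <- pair_key(obs$entries$i, obs$entries$j, n) * (n_layers + 1) +
      obs$entries$layer
    item_key <- pair_key(items$i, items$j, n) * (n_layers + 1) + items$layer
    items <- items[!(item_key %in% obs_key), , drop = FALSE]
  }
  rownames(items) <- NULL
  structure(list(items = items, n_items = nrow(items)), class = "test_set")
}

#' Vertex-sampled partial observations
#'
#' Draws `n = round(sqrt(c) * N)` nodes uniformly without replacement and
#' observes, for every aggregate edge inside the sampled node set, its 0/1
#' membership in every layer. The induced subgraph covers about a fraction
#' `c` of the `L |A|` potential entries.
#'
#' @param m a [multiplex_network] (the ground truth being sampled).
#' @param c nominal observation fraction in `[0, 1]`.
#' @param seed optional integer seed; the ambient RNG stream is untouched.
#' @return an [observation_set]; the realized fraction is its `c` field.
#' @export
sample_observations_vertex <- function(m, c, seed = NULL) {
  stopifnot(inherits(m, "multiplex_network"), c >= 0, c <= 1)
  agg <- aggregate_or(m)
  with_seed(seed, {
    n_pick <- round(sqrt(c) * m$n_nodes)
    nodes <- if (n_pick > 0) sample.int(m$n_nodes, n_pick) else integer(0)
    observe_within(m, agg, nodes, layers = seq_len(m$n_layers))
  })
}

#' Per-layer budgeted partial observations
#'
#' Independent vertex sampling per layer: layer `a` receives its own set of
#' `round(sqrt(c_a) * N)` sampled nodes and only that layer's memberships are
#' observed within the set. With `shared_nodes = TRUE` a single node set drawn
#' at the larger size is reused, nested, across layers.
#'
#' @param m a [multiplex_network] with two layers.
#' @param c1,c2 per-layer nominal observation fractions in `[0, 1]`.
#' @param seed optional integer seed.
#' @param shared_nodes reuse one node ordering across layers (nested sets).
#' @return an [observation_set] whose `c_layer` holds the realized per-layer
#'   fractions.
#' @export
sample_observations_budget <- function(m, c1, c2, seed = NULL,
                                       shared_nodes = FALSE) {
  stopifnot(inherits(m, "multiplex_network"), m$n_layers == 2,
            c1 >= 0, c1 <= 1, c2 >= 0, c2 <= 1)
  agg <- aggregate_or(m)
  with_seed(seed, {
    counts <- round(sqrt(c(c1, c2)) * m$n_nodes)
    perm <- sample.int(m$n_nodes)    # one draw keeps shared mode nested
    parts <- lapply(1:2, function(a) {
      nodes <- if (shared_nodes) {
        perm[seq_len(counts[a])]
      } else {
        sample.int(m$n_nodes, counts[a])
      }
      obs <- observe_within(m, agg, nodes, layers = a)
      obs$entries
    })
    observation_set(do.call(rbind, parts), agg, m$n_layers)
  })
}

# Observe the memberships of every aggregate edge whose endpoints both lie in
# `nodes`, for the given layers.
observe_within <- function(m, agg, nodes, layers) {
  n <- m$n_nodes
  inside <- logical(n)
  inside[nodes] <- TRUE
  sel <- inside[agg$edges[, 1]] & inside[agg$edges[, 2]]
  pairs <- agg$edges[sel, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(observation_set(NULL, agg, m$n_layers))
  }
  entries <- do.call(rbind, lapply(layers, function(a) {
    lay_keys <- pair_key(m$layers[[a]][, 1], m$layers[[a]][, 2], n)
    val <- pair_key(pairs[, 1], pairs[, 2], n) %in% lay_keys
    data.frame(i = pairs[, 1], j = pairs[, 2], layer = rep(a, nrow(pairs)),
               value = as.integer(val))
  }))
  observation_set(entries, agg, m$n_layers)
}
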