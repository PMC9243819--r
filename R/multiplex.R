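#' Construct a multiplex network
#'
#' A multiplex network is a set of `L` layers (link types) sharing one node
#' set of size `n_nodes`. Each layer is an undirected, unweighted simple
#' graph stored as a canonical edge table (two integer columns, `i < j`,
#' sorted, deduplicated, no self-loops).
#'
#' @param layers list of layers; each layer is a two-column matrix or data
#'   frame of node-index pairs (both orientations accepted, duplicates
#'   dropped). An empty layer may be given as `NULL` or a zero-row matrix.
#' @param n_nodes number of nodes `N` shared by all layers.
#' @param labels optional character vector of length `n_nodes` mapping
#'   internal indices `1..N` back to external node labels.
#'
#' @return an object of class `multiplex_network` with fields `n_nodes`,
#'   `n_layers`, `layers` (list of canonical edge matrices) and `labels`.
#' @examples
#' m <- multiplex_network(list(cbind(1, 2), cbind(2, 3)), n_nodes = 3)
#' aggregate_or(m)
#' @export
multiplex_network <- function(layers, n_nodes, labels = NULL) {
  if (!is.list(layers) || length(layers) < 1) {
    stop("`layers` must be a non-empty list of edge tables", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1) {
    stop("`n_nodes` must be a positive integer", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n_nodes) {
    stop("`labels` must have length `n_nodes`", call. = FALSE)
  }
  layers <- lapply(layers, canonicalize_edges, n_nodes = n_nodes)
  structure(
    list(
      n_nodes = n_nodes,
      n_layers = length(layers),
      layers = layers,
      labels = labels
    ),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("Multiplex network:", x$n_nodes, "nodes,", x$n_layers, "layers\n")
  for (a in seq_len(x$n_layers)) {
    cat(sprintf("  layer %d: %d edges (<k> = %.3f)\n", a, nrow(x$layers[[a]]),
                2 * nrow(x$layers[[a]]) / x$n_nodes))
  }
  invisible(x)
}

#' Aggregate a multiplex network by the OR mechanism
#'
#' The aggregate monoplex topology has an edge between `i` and `j` whenever at
#' least one layer does: `A_ij = 1 - prod_a (1 - M_ij^a)`.
#'
#' @param m a [multiplex_network].
#' @return an object of class `aggregate_topology` with fields `n_nodes`,
#'   `edges` (canonical edge matrix) and `n_edges`.
#' @export
aggregate_or <- function(m) {
  stopifnot(inherits(m, "multiplex_network"))
  all_edges <- do.call(rbind, m$layers)
  edges <- canonicalize_edges(all_edges, m$n_nodes)
  aggregate_topology(edges, m$n_nodes)
}

#' Construct an aggregate topology from an edge table
#'
#' @param edges two-column node-pair table (canonicalized on input).
#' @param n_nodes number of nodes.
#' @return an `aggregate_topology` object.
#' @export
aggregate_topology <- function(edges, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  edges <- canonicalize_edges(edges, n_nodes)
  structure(
    list(n_nodes = n_nodes, edges = edges, n_edges = nrow(edges)),
    class = "aggregate_topology"
  )
}

#' @export
print.aggregate_topology <- function(x, ...) {
  cat("Aggregate topology:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  invisible(x)
}

#' Structural characteristics of a two-layer multiplex network
#'
#' Computes the per-layer mean degrees, the ratio of average degrees
#' `r = <k_1>/<k_2>` after ordering the layers so that `<k_1> <= <k_2>`
#' (hence `0 < r <= 1`), the edge overlap `v` (Jaccard index of the two edge
#' sets), and the cosine similarity of the two degree-sequence vectors.
#' `r`, `v` and the cosine are defined for `L = 2`; mean degrees are returned
#' for any `L`.
#'
#' @param m a [multiplex_network].
#' @return a list with `mean_degrees`, and for two-layer networks `r`, `v`,
#'   `cosine` and `layer_order` (the permutation placing the sparser layer
#'   first).
#' @export
characterize_multiplex <- function(m) {
  stopifnot(inherits(m, "multiplex_network"))
  kbar <- vapply(m$layers, function(e) 2 * nrow(e) / m$n_nodes, numeric(1))
  out <- list(mean_degrees = kbar)
  if (m$n_layers != 2) {
    return(out)
  }
  ord <- order(kbar)          # sparser layer first so that r <= 1
  e1 <- m$layers[[ord[1]]]
  e2 <- m$layers[[ord[2]]]
  if (nrow(e1) == 0 || nrow(e2) == 0) {
    stop("degree ratio r undefined: a layer has zero edges", call. = FALSE)
  }
  k1 <- pair_key(e1[, 1], e1[, 2], m$n_nodes)
  k2 <- pair_key(e2[, 1], e2[, 2], m$n_nodes)
  inter <- length(intersect(k1, k2))
  v <- inter / (length(k1) + length(k2) - inter)
  d1 <- edge_degrees(e1, m$n_nodes)
  d2 <- edge_degrees(e2, m$n_nodes)
  cosine <- sum(d1 * d2) / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
  out$r <- kbar[ord[1]] / kbar[ord[2]]
  out$v <- v
  out$cosine <- cosine
  out$layer_order <- ord
  out
}
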