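# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Unique key for an unordered node pair with i < j; used to match edge tables.
pair_key <- function(i, j, n_nodes) {
  (pmin(i, j) - 1) * as.double(n_nodes) + pmax(i, j)
}

# Map linear indices t in 1..N(N-1)/2 to unordered pairs (i < j), ordered by
# j then i: (1,2), (1,3), (2,3), (1,4), ... Used to draw uniform random pairs
# without materializing all of them.
pair_from_index <- function(t, n_nodes) {
  j <- ceiling((1 + sqrt(1 + 8 * as.double(t))) / 2)
  # guard against floating-point boundary misses
  j <- j - (((j - 1) * (j - 2)) %/% 2 >= t)
  j <- j + ((j * (j - 1)) %/% 2 < t)
  i <- t - ((j - 1) * (j - 2)) %/% 2
  cbind(i = as.integer(i), j = as.integer(j))
}

# Canonicalize an edge table: 2 columns, i < j, integer, deduplicated, sorted
# by (i, j); self-loops are an error (all adjacencies have zero diagonal).
canonicalize_edges <- function(edges, n_nodes) {
  if (is.null(edges) || NROW(edges) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L) || any(edges > n_nodes)) {
    stop("edge endpoints must be integers in 1..n_nodes", call. = FALSE)
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  ij <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ij <- ij[!duplicated(pair_key(ij[, 1], ij[, 2], n_nodes)), , drop = FALSE]
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij
}

# Degree sequence of an edge table over 1..n_nodes.
edge_degrees <- function(edges, n_nodes) {
  tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
}
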