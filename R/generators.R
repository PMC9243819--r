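#' Generate a two-layer multiplex network with prescribed degree ratio and
#' edge overlap
#'
#' Layer 1 is an Erdős–Rényi graph with edge probability `p = 5/(N-1)`
#' (mean degree 5). Layer 2 is drawn pairwise conditionally on layer 1 so
#' that, in expectation, the degree ratio equals `r` and the Jaccard edge
#' overlap equals `v`:
#' `P(M2 = 1 | M1 = 1) = v (r + 1) / (r (v + 1))` and
#' `P(M2 = 1 | M1 = 0) = 5/(N-6) * (1 - v r) / (r (v + 1))`,
#' giving `E<k_1> = 5`, `E<k_2> = 5/r`, `E(r) = r`, `E(v) = v`.
#'
#' @param n_nodes number of nodes `N > 6`.
#' @param r target ratio of average degrees, `0 < r <= 1`.
#' @param v target edge overlap, `0 <= v <= r` (larger overlaps would require
#'   a conditional probability above 1).
#' @param seed optional integer seed.
#' @return a two-layer [multiplex_network].
#' @examples
#' m <- generate_er_pair(200, r = 0.5, v = 0.2, seed = 1)
#' characterize_multiplex(m)
#' @export
generate_er_pair <- function(n_nodes, r, v, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes <= 6) stop("`n_nodes` must exceed 6", call. = FALSE)
  if (r <= 0 || r > 1) stop("`r` must lie in (0, 1]", call. = FALSE)
  if (v < 0 || v > r) {
    stop("`v` must lie in [0, r]: larger overlaps make the conditional edge probability exceed 1",
         call. = FALSE)
  }
  p1 <- 5 / (n_nodes - 1)
  p11 <- v * (r + 1) / (r * (v + 1))
  p01 <- 5 / (n_nodes - 6) * (1 - v * r) / (r * (v + 1))
  if (p01 > 1) {
    stop("infeasible (r, v, N): P(M2 = 1 | M1 = 0) exceeds 1", call. = FALSE)
  }
  with_seed(seed, {
    n_pairs <- n_nodes * (n_nodes - 1) / 2
    idx1 <- sample_pair_indices(n_pairs, p1)
    e1 <- pair_from_index(idx1, n_nodes)
    # layer 2: thin layer-1 edges with p11, add layer-1 non-edges with p01
    keep <- idx1[stats::runif(length(idx1)) < p11]
    idx01 <- sample_complement_indices(n_pairs, idx1, p01)
    e2 <- pair_from_index(c(keep, idx01), n_nodes)
    multiplex_network(list(e1, e2), n_nodes)
  })
}

# Draw the indices of Bernoulli(p) successes among 1..n_pairs without
# enumerating the pairs: binomial count, then a uniform sample of indices.
sample_pair_indices <- function(n_pairs, p) {
  k <- stats::rbinom(1, n_pairs, p)
  if (k == 0) return(integer(0))
  sort(sample.int(n_pairs, k))
}

# Same, restricted to the complement of `excluded` (rejection sampling; the
# excluded set is small relative to n_pairs in the sparse regime).
sample_complement_indices <- function(n_pairs, excluded, p) {
  n_avail <- n_pairs - length(excluded)
  k <- stats::rbinom(1, n_avail, p)
  if (k == 0) return(integer(0))
  picked <- integer(0)
  while (length(picked) < k) {
    cand <- sample.int(n_pairs, min(n_pairs, ceiling((k - length(picked)) * 1.5) + 8))
    cand <- setdiff(cand, c(excluded, picked))
    picked <- c(picked, cand)
  }
  sort(picked[seq_len(k)])
}

#' Generate a multiplex network from prescribed degree sequences
#'
#' Each layer is drawn with independent Bernoulli edges under the
#' configuration-model law `P(M_ij = 1) = d(i) d(j) / (||d||_1 - 1)`, so that
#' the expected degree of node `i` is approximately `d(i)`.
#'
#' @param d1,d2 positive numeric vectors of expected degrees (equal length
#'   `N`); additional layers may be supplied via `more`.
#' @param more optional list of further degree sequences (layers 3, 4, ...).
#' @param seed optional integer seed.
#' @return a [multiplex_network] with one layer per degree sequence.
#' @export
generate_from_degree_sequences <- function(d1, d2, more = NULL, seed = NULL) {
  seqs <- c(list(d1, d2), more)
  n <- length(d1)
  if (!all(vapply(seqs, length, 1L) == n)) {
    stop("all degree sequences must have the same length", call. = FALSE)
  }
  for (d in seqs) {
    if (any(d < 0)) stop("degree sequences must be non-negative", call. = FALSE)
    s <- sum(d)
    top <- sort(d, decreasing = TRUE)[1:2]
    if (s > 1 && top[1] * top[2] / (s - 1) > 1) {
      stop("infeasible degree sequence: a pair probability exceeds 1", call. = FALSE)
    }
  }
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # i < j pairs
  with_seed(seed, {
    layers <- lapply(seqs, function(d) {
      s <- sum(d)
      if (s <= 1) return(NULL)
      p <- d[ut[, 1]] * d[ut[, 2]] / (s - 1)
      ut[stats::runif(nrow(ut)) < p, , drop = FALSE]
    })
    multiplex_network(layers, n)
  })
}

#' Random degree-sequence pair with a target cosine similarity
#'
#' Draws two positive, heavy-tailed degree sequences whose cosine similarity
#' hits `target_cosine` within `tol`. A low-cosine companion sequence is
#' built by anti-aligning magnitudes with the first sequence, then blended
#' toward it; the blend weight is bisected until the cosine matches. Both
#' sequences are scaled to mean degree `mean_degree`.
#'
#' @param n_nodes number of nodes.
#' @param target_cosine target in (0, 1).
#' @param mean_degree common mean degree of the two sequences (default 5).
#' @param tol acceptance tolerance on the realized cosine (default 0.02).
#' @param seed optional integer seed.
#' @param max_tries base-draw retries before declaring the target infeasible.
#' @return list with `d1`, `d2` and the realized `cosine`.
#' @export
make_degree_sequences <- function(n_nodes, target_cosine, mean_degree = 5,
                                  tol = 0.02, seed = NULL, max_tries = 50) {
  if (target_cosine <= 0 || target_cosine >= 1) {
    stop("`target_cosine` must lie in (0, 1)", call. = FALSE)
  }
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  s_total <- mean_degree * n_nodes
  cap <- 0.9 * sqrt(s_total - 1)   # keeps all pair probabilities below 1
  draw <- function() {
    x <- stats::runif(n_nodes)^(-1)            # heavy-tailed positive draws
    x <- x * s_total / sum(x)
    for (it in 1:50) {                         # cap hubs, restore the mean
      x <- pmin(x, cap)
      x <- x * s_total / sum(x)
      if (max(x) <= cap * (1 + 1e-9)) break
    }
    pmin(x, cap)
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      d1 <- draw()
      u <- sort(draw(), decreasing = TRUE)[rank(d1, ties.method = "first")]
      lo <- 0
      hi <- 1
      if (cosine(u, d1) > target_cosine) next   # base pair not dissimilar enough
      for (it in 1:60) {                        # cosine(blend) is monotone in t
        t <- (lo + hi) / 2
        d2 <- (1 - t) * u + t * d1
        if (cosine(d2, d1) < target_cosine) lo <- t else hi <- t
      }
      d2 <- (1 - hi) * u + hi * d1
      if (abs(cosine(d2, d1) - target_cosine) <= tol) {
        d1 <- d1 * s_total / sum(d1)
        d2 <- d2 * s_total / sum(d2)
        feasible <- vapply(list(d1, d2), function(d) {
          top <- sort(d, decreasing = TRUE)[1:2]
          top[1] * top[2] / (sum(d) - 1) <= 1
        }, logical(1))
        if (!all(feasible)) next
        return(list(d1 = d1, d2 = d2, cosine = cosine(d1, d2)))
      }
    }
    stop(sprintf("could not reach cosine %.3f at N = %d after %d tries",
                 target_cosine, n_nodes, max_tries), call. = FALSE)
  })
}
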