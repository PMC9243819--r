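#' Binarize a link posterior into a point-estimate multiplex network
#'
#' A layer edge is kept when its reliability exceeds the threshold `q`.
#' Entries exactly at the threshold are kept with probability 1/2 under the
#' run seed; this rule is meant for feeding reconstructed networks into
#' dynamics — evaluation metrics use the half-contribution rule instead.
#'
#' @param posterior a `link_posterior`.
#' @param q threshold in (0, 1); defaults to 0.5 (no prior reason to favor
#'   either class).
#' @param seed optional integer seed (used only to break exact ties).
#' @return a [multiplex_network].
#' @export
binarize_reconstruction <- function(posterior, q = 0.5, seed = NULL) {
  stopifnot(inherits(posterior, "link_posterior"), q > 0, q < 1)
  Q <- posterior$marginals
  with_seed(seed, {
    keep <- Q > q
    ties <- which(Q == q)
    if (length(ties) > 0) {
      keep[ties] <- stats::runif(length(ties)) < 0.5
    }
    layers <- lapply(seq_len(posterior$n_layers), function(a) {
      posterior$edges[keep[, a], , drop = FALSE]
    })
    multiplex_network(layers, posterior$n_nodes)
  })
}

#' Expected degree distribution of a reconstructed layer
#'
#' The posterior expectation `E(p_a) = sum_M Q(M) p_a(M)` of the degree
#' distribution in layer `a`, estimated by Monte Carlo: per-edge membership
#' states are drawn independently from each edge's categorical posterior and
#' the layer's degree histogram is averaged over draws. When every
#' reliability is already 0 or 1 the result is exact and `samples` is
#' ignored.
#'
#' @param posterior a `link_posterior` with `state_probs` (as returned by
#'   [em_e_step()] / [reconstruct_em()]).
#' @param layer layer index.
#' @param samples number of Monte-Carlo draws (default 200).
#' @param seed optional integer seed.
#' @return data frame with columns `degree` (0, 1, ...) and `prob`.
#' @export
expected_degree_distribution <- function(posterior, layer, samples = 200,
                                         seed = NULL) {
  stopifnot(inherits(posterior, "link_posterior"), samples >= 1)
  n <- posterior$n_nodes
  edges <- posterior$edges
  Q <- posterior$marginals[, layer]
  if (all(Q %in% c(0, 1))) {
    deg <- edge_degrees(edges[Q == 1, , drop = FALSE], n)
    counts <- tabulate(deg + 1L, nbins = max(deg) + 1L)
    return(data.frame(degree = seq_along(counts) - 1L, prob = counts / n))
  }
  P <- posterior$state_probs
  if (is.null(P)) stop("posterior lacks joint state probabilities", call. = FALSE)
  cum <- t(apply(P, 1, cumsum))
  member <- posterior$states[, layer]
  m <- nrow(edges)
  acc <- numeric(n + 1)   # histogram over degrees 0..n
  with_seed(seed, {
    for (s in seq_len(samples)) {
      state <- rowSums(stats::runif(m) > cum) + 1L
      present <- member[state] == 1
      deg <- edge_degrees(edges[present, , drop = FALSE], n)
      acc <- acc + tabulate(deg + 1L, nbins = n + 1)
    }
  })
  prob <- acc / (samples * n)
  kmax <- max(which(prob > 0), 1L)
  data.frame(degree = 0:(kmax - 1L), prob = prob[seq_len(kmax)])
}
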