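# Validation dynamics run on true or reconstructed multiplex networks.

# igraph handle per layer with exactly n_nodes vertices
layer_graphs <- function(m) {
  lapply(m$layers, function(e) {
    g <- igraph::make_empty_graph(n = m$n_nodes, directed = FALSE)
    if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
    g
  })
}

# Largest-component membership of the subgraph induced by `active`.
giant_members <- function(g, active) {
  sub <- igraph::induced_subgraph(g, active)
  comp <- igraph::components(sub)
  if (comp$no == 0) return(integer(0))
  active[comp$membership == which.max(comp$csize)]
}

#' Interdependent percolation and the giant mutually connected component
#'
#' Nodes in layer 1 are removed with probability `1 - p`; nodes outside the
#' giant component of either layer (restricted to surviving nodes) fail, and
#' failures propagate to their counterparts in the other layer until a fixed
#' point — the cascading-failure process of interdependent networks. The
#' surviving giant mutually connected component (GMCC) fraction is averaged
#' over trials for each occupation probability, and the critical threshold
#' `p_c` is estimated as the smallest grid `p` whose mean GMCC exceeds
#' `cutoff`.
#'
#' @param m a two-layer [multiplex_network].
#' @param p occupation probabilities (vector grid in \[0, 1\]).
#' @param trials Monte-Carlo trials per grid point.
#' @param seed optional integer seed.
#' @param cutoff finite-size GMCC cutoff defining `p_c` (default `10 / N`).
#' @return a `percolation_result` with `p`, `gmcc` (mean fraction per `p`),
#'   `p_c` (`NA` when the curve never exceeds the cutoff), `trials`,
#'   `cutoff`.
#' @export
interdependent_percolation <- function(m, p, trials = 20, seed = NULL,
                                       cutoff = NULL) {
  stopifnot(inherits(m, "multiplex_network"), m$n_layers == 2, trials >= 1,
            all(p >= 0 & p <= 1))
  n <- m$n_nodes
  if (is.null(cutoff)) cutoff <- 10 / n
  gs <- layer_graphs(m)
  mean_gmcc <- with_seed(seed, {
    vapply(p, function(pp) {
      sizes <- vapply(seq_len(trials), function(t) {
        active <- which(stats::runif(n) < pp)
        repeat {
          if (length(active) == 0) break
          new_active <- giant_members(gs[[1]], active)
          new_active <- giant_members(gs[[2]], new_active)
          if (length(new_active) == length(active)) break
          active <- new_active
        }
        length(active) / n
      }, numeric(1))
      mean(sizes)
    }, numeric(1))
  })
  above <- which(mean_gmcc > cutoff)
  structure(
    list(p = p, gmcc = mean_gmcc,
         p_c = if (length(above) > 0) p[min(above)] else NA_real_,
         trials = trials, cutoff = cutoff),
    class = "percolation_result"
  )
}

#' Random-walk coverage on a multiplex network
#'
#' Walkers start at uniformly random (node, layer) positions. At each step a
#' walker switches to its counterpart in the other layer with probability
#' `p_inter`, moves to a uniform intralayer neighbor with probability
#' `p_intra` (staying put when isolated in its layer), and otherwise stays.
#' Coverage is the fraction of nodes visited by any walker, in any layer, up
#' to time `t`.
#'
#' @param m a [multiplex_network].
#' @param n_walkers number of walkers.
#' @param p_intra,p_inter step probabilities, `p_intra + p_inter <= 1`.
#' @param t_max time horizon.
#' @param seed optional integer seed.
#' @return a `walk_result` with `t` (0..t_max), `coverage`, and the
#'   parameters.
#' @export
random_walk_coverage <- function(m, n_walkers, p_intra = 0.8, p_inter = 0.2,
                                 t_max = 100, seed = NULL) {
  stopifnot(inherits(m, "multiplex_network"), n_walkers >= 1, t_max >= 0,
            p_intra >= 0, p_inter >= 0, p_intra + p_inter <= 1)
  n <- m$n_nodes
  if (n == 0 || all(vapply(m$layers, nrow, 1L) == 0)) {
    stop("random walk undefined on an empty network", call. = FALSE)
  }
  nbrs <- lapply(m$layers, function(e) {
    adj <- vector("list", n)
    if (nrow(e) > 0) {
      half <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
      adj[as.integer(names(half))] <- half
    }
    adj
  })
  with_seed(seed, {
    node <- sample.int(n, n_walkers, replace = TRUE)
    layer <- sample.int(m$n_layers, n_walkers, replace = TRUE)
    visited <- logical(n)
    visited[node] <- TRUE
    coverage <- numeric(t_max + 1)
    coverage[1] <- mean(visited)
    if (t_max > 0) {
      for (t in seq_len(t_max)) {
        u <- stats::runif(n_walkers)
        for (w in seq_len(n_walkers)) {
          if (u[w] < p_inter) {
            layer[w] <- (layer[w] %% m$n_layers) + 1L   # counterpart switch
          } else if (u[w] < p_inter + p_intra) {
            nb <- nbrs[[layer[w]]][[node[w]]]
            if (length(nb) > 0) {
              node[w] <- nb[sample.int(length(nb), 1)]
            }
          }
        }
        visited[node] <- TRUE
        coverage[t + 1] <- mean(visited)
      }
    }
    structure(
      list(t = 0:t_max, coverage = coverage, n_walkers = n_walkers,
           p_intra = p_intra, p_inter = p_inter),
      class = "walk_result"
    )
  })
}

#' Susceptible-infected spreading on a temporal network
#'
#' The layers are ordered time slots: at step `t` the contact graph is layer
#' `t`, every infected node independently infects each susceptible neighbor
#' with probability `lambda`, and infection persists across slots (the
#' interlayer coupling links counterparts at adjacent times). A fraction
#' `source_fraction` of nodes (default 5%) is infected at `t = 0`.
#'
#' @param layers a [multiplex_network] whose layers are time slots, or a
#'   list of edge tables plus `n_nodes`.
#' @param lambda per-contact infection probability in \[0, 1\].
#' @param t_max horizon, at most the number of layers.
#' @param source_fraction initially infected fraction.
#' @param n_nodes required when `layers` is a plain list.
#' @param seed optional integer seed.
#' @return a `spread_result` with `t` (0..t_max), `infected` (fractions),
#'   `lambda`, `source_fraction`, `sources`.
#' @export
si_spreading_temporal <- function(layers, lambda, t_max,
                                  source_fraction = 0.05, n_nodes = NULL,
                                  seed = NULL) {
  if (inherits(layers, "multiplex_network")) {
    n_nodes <- layers$n_nodes
    layers <- layers$layers
  }
  stopifnot(!is.null(n_nodes), lambda >= 0, lambda <= 1,
            t_max >= 0, t_max <= length(layers))
  with_seed(seed, {
    n_src <- round(source_fraction * n_nodes)
    infected <- logical(n_nodes)
    infected[sample.int(n_nodes, n_src)] <- TRUE
    frac <- numeric(t_max + 1)
    frac[1] <- mean(infected)
    for (t in seq_len(t_max)) {
      e <- layers[[t]]
      if (nrow(e) > 0 && lambda > 0) {
        ii <- infected[e[, 1]]
        jj <- infected[e[, 2]]
        # one independent transmission chance per infected-susceptible contact
        hit_j <- e[ii & !jj, 2]
        hit_i <- e[!ii & jj, 1]
        targets <- c(hit_j, hit_i)
        if (length(targets) > 0) {
          success <- targets[stats::runif(length(targets)) < lambda]
          infected[success] <- TRUE
        }
      }
      frac[t + 1] <- mean(infected)
    }
    structure(
      list(t = 0:t_max, infected = frac, lambda = lambda,
           source_fraction = source_fraction, sources = n_src),
      class = "spread_result"
    )
  })
}
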