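# Expectation-maximization engine for the configuration-model likelihood.
#
# The generative law is independent Bernoulli edges per layer with
#   pi_ij^a = min(1, d^a(i) d^a(j) / (S_a - 1)),   S_a = ||d^a||_1,
# the same law the synthetic generators use. The joint likelihood of
# (A, Gamma, M) factorizes over node pairs, which is what makes both the
# E-step (per-edge categorical posteriors over the 2^L - 1 layer-membership
# states) and the whole algorithm polynomial instead of exponential.

#' Degree parameters of the configuration model
#'
#' @param sequences numeric matrix (`N` rows, `L` columns) or list of `L`
#'   numeric vectors of non-negative degree parameters.
#' @return a `degree_params` object with fields `d` (N x L matrix) and `s`
#'   (per-layer sums).
#' @export
degree_params <- function(sequences) {
  d <- if (is.list(sequences)) do.call(cbind, sequences) else as.matrix(sequences)
  if (any(d < 0)) stop("degree parameters must be non-negative", call. = FALSE)
  structure(list(d = d, s = colSums(d)), class = "degree_params")
}

#' Prior edge probability under the configuration model
#'
#' `pi = min(1, d^a(i) d^a(j) / (S_a - 1))`; zero when either endpoint
#' parameter is zero or when `S_a <= 1`.
#'
#' @param params a [degree_params].
#' @param i,j node indices (vectorized, `i != j`).
#' @param layer layer index.
#' @return probabilities in `[0, 1]`.
#' @export
edge_prior_prob <- function(params, i, j, layer) {
  stopifnot(inherits(params, "degree_params"))
  if (any(i == j)) stop("self-pairs have no edge probability", call. = FALSE)
  s <- params$s[layer]
  if (s <= 1) return(rep(0, length(i)))
  pmin(1, params$d[i, layer] * params$d[j, layer] / (s - 1))
}

# Prior probabilities for every aggregate edge: m x L matrix.
prior_matrix <- function(params, edges) {
  L <- ncol(params$d)
  sapply(seq_len(L), function(a) {
    edge_prior_prob(params, edges[, 1], edges[, 2], a)
  }, simplify = "array") |> matrix(nrow = nrow(edges), ncol = L)
}

# All 2^L - 1 nonzero layer-membership states, one row per state.
membership_states <- function(n_layers) {
  g <- as.matrix(expand.grid(rep(list(0:1), n_layers)))
  g <- g[rowSums(g) > 0, , drop = FALSE]
  dimnames(g) <- NULL
  g
}

# m x L matrix of observed values (NA where unobserved).
observed_matrix <- function(aggregate, obs) {
  m <- aggregate$n_edges
  L <- obs$n_layers
  O <- matrix(NA_integer_, m, L)
  if (nrow(obs$entries) > 0) {
    n <- aggregate$n_nodes
    agg_key <- pair_key(aggregate$edges[, 1], aggregate$edges[, 2], n)
    row <- match(pair_key(obs$entries$i, obs$entries$j, n), agg_key)
    O[cbind(row, obs$entries$layer)] <- obs$entries$value
  }
  O
}

#' E-step: per-edge posterior over layer-membership states
#'
#' For every aggregate edge the posterior over the `2^L - 1` states with at
#' least one layer present is the product of per-layer Bernoulli priors,
#' restricted to states consistent with the observed values, normalized.
#' Edges whose every consistent state has zero prior mass receive the uniform
#' distribution over consistent states (this keeps early EM iterations from
#' dividing by zero); pairs outside the aggregate have no posterior rows.
#'
#' @param aggregate an [aggregate_topology].
#' @param obs an [observation_set].
#' @param params a [degree_params].
#' @return a `link_posterior`: fields `edges`, `n_nodes`, `n_layers`,
#'   `states` (state matrix), `state_probs` (m x K), `marginals` (m x L link
#'   reliabilities `Q_ij^a`), `observed` (m x L, NA where unobserved) and
#'   `n_degenerate` (count of zero-mass edges resolved uniformly).
#' @export
em_e_step <- function(aggregate, obs, params) {
  stopifnot(inherits(aggregate, "aggregate_topology"),
            inherits(obs, "observation_set"),
            inherits(params, "degree_params"))
  L <- obs$n_layers
  states <- membership_states(L)
  K <- nrow(states)
  m <- aggregate$n_edges
  pi_mat <- prior_matrix(params, aggregate$edges)
  O <- observed_matrix(aggregate, obs)
  W <- matrix(1, m, K)
  C <- matrix(TRUE, m, K)
  for (k in seq_len(K)) {
    for (a in seq_len(L)) {
      W[, k] <- W[, k] * (if (states[k, a] == 1) pi_mat[, a] else 1 - pi_mat[, a])
      o <- O[, a]
      C[, k] <- C[, k] & (is.na(o) | o == states[k, a])
    }
  }
  if (m > 0 && any(rowSums(C) == 0)) {
    stop("an aggregate edge has no membership state consistent with the observations",
         call. = FALSE)
  }
  W <- W * C
  z <- rowSums(W)
  degenerate <- which(z == 0)
  if (length(degenerate) > 0) {
    W[degenerate, ] <- C[degenerate, , drop = FALSE] * 1
    z[degenerate] <- rowSums(C[degenerate, , drop = FALSE])
  }
  P <- W / z
  structure(
    list(
      edges = aggregate$edges,
      n_nodes = aggregate$n_nodes,
      n_layers = L,
      states = states,
      state_probs = P,
      marginals = P %*% states,
      observed = O,
      n_degenerate = length(degenerate)
    ),
    class = "link_posterior"
  )
}

#' @export
print.link_posterior <- function(x, ...) {
  cat(sprintf("Link posterior: %d aggregate edges x %d layers\n",
              nrow(x$edges), x$n_layers))
  invisible(x)
}

#' M-step: expected-degree update of the configuration parameters
#'
#' `d^a(i) = sum_j q_ij^a`, where `q` is the observed value for entries in
#' the observation set and the posterior reliability otherwise — the
#' expected-degree maximizer of the posterior-expected log-likelihood for
#' the sparse configuration likelihood.
#'
#' @param posterior a `link_posterior` from [em_e_step()].
#' @return a [degree_params].
#' @export
em_m_step <- function(posterior) {
  stopifnot(inherits(posterior, "link_posterior"))
  q <- posterior$marginals
  obs <- posterior$observed
  q[!is.na(obs)] <- obs[!is.na(obs)]
  n <- posterior$n_nodes
  L <- posterior$n_layers
  d <- matrix(0, n, L)
  idx <- c(posterior$edges[, 1], posterior$edges[, 2])
  for (a in seq_len(L)) {
    acc <- rowsum(c(q[, a], q[, a]), idx)
    d[as.integer(rownames(acc)), a] <- acc
  }
  degree_params(d)
}

# Lower bound J(Q, theta) of the log-likelihood: the posterior-expected joint
# log-likelihood plus the entropy of Q. Split into a theta-only non-edge part
# (the O(N^2) sum over pairs outside the aggregate, cacheable across E-steps)
# and a Q-dependent edge part. Probabilities are clipped away from {0, 1}
# before taking logs.
em_nonedge_term <- function(aggregate, params) {
  eps <- 1e-12
  d <- params$d
  edges <- aggregate$edges
  nonedge <- 0
  for (a in seq_len(ncol(d))) {
    s <- params$s[a]
    if (s <= 1) next
    pm <- tcrossprod(d[, a]) / (s - 1)
    pm[pm > 1 - eps] <- 1 - eps
    lp <- log1p(-pm)
    all_pairs <- (sum(lp) - sum(diag(lp))) / 2
    nonedge <- nonedge + all_pairs - sum(lp[edges])
  }
  nonedge
}

em_edge_term <- function(aggregate, posterior, params) {
  eps <- 1e-12
  L <- ncol(params$d)
  pi_mat <- pmin(pmax(prior_matrix(params, aggregate$edges), eps), 1 - eps)
  states <- posterior$states
  P <- posterior$state_probs
  logw <- matrix(0, nrow(aggregate$edges), nrow(states))
  for (k in seq_len(nrow(states))) {
    for (a in seq_len(L)) {
      logw[, k] <- logw[, k] +
        (if (states[k, a] == 1) log(pi_mat[, a]) else log1p(-pi_mat[, a]))
    }
  }
  plogp <- P * log(pmax(P, eps))
  sum(P * logw) - sum(plogp[P > 0])
}

em_lower_bound <- function(aggregate, posterior, params) {
  em_nonedge_term(aggregate, params) +
    em_edge_term(aggregate, posterior, params)
}

#' Control settings for the EM reconstruction
#'
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute convergence tolerance on the lower bound `J`.
#' @param restarts number of random initializations; the run with the best
#'   final `J` is returned.
#' @param init_scale upper limit of the uniform degree initialization;
#'   defaults to the aggregate mean degree per layer, `2 |A| / (N L)`.
#' @param seed optional integer seed for initialization.
#' @return an `em_control` list.
#' @export
em_control <- function(max_iter = 500, tol = 1e-8, restarts = 5,
                       init_scale = NULL, seed = NULL) {
  stopifnot(max_iter >= 1, tol > 0, restarts >= 1)
  structure(list(max_iter = max_iter, tol = tol, restarts = restarts,
                 init_scale = init_scale, seed = seed),
            class = "em_control")
}

#' Reconstruct a multiplex network by expectation-maximization
#'
#' Alternates [em_e_step()] and [em_m_step()] from random initial degree
#' parameters until the log-likelihood lower bound `J` changes by less than
#' `control$tol`, for `control$restarts` random initializations, and returns
#' the run with the largest final `J`. Because the closed-form M-step is the
#' sparse-regime maximizer rather than the exact one, each M-step is
#' safeguarded: if the proposed update would lower `J`, it is contracted
#' toward the previous parameters until `J` is non-decreasing (a generalized
#' EM step), so the returned trace is monotone by construction.
#'
#' @param aggregate an [aggregate_topology].
#' @param obs an [observation_set] over `aggregate`.
#' @param n_layers number of layers `L >= 1`.
#' @param control an [em_control].
#' @return an `em_result` with fields `params`, `posterior`, `trace` (lower
#'   bound per iteration of the best restart), `logJ_restarts` (final `J` per
#'   restart), `best_restart`, `converged`, `n_iter`.
#' @examples
#' m <- generate_er_pair(60, r = 0.8, v = 0.2, seed = 1)
#' a <- aggregate_or(m)
#' g <- sample_observations_vertex(m, c = 0.4, seed = 2)
#' fit <- reconstruct_em(a, g, n_layers = 2,
#'                       control = em_control(restarts = 2, seed = 3))
#' head(fit$posterior$marginals)
#' @export
reconstruct_em <- function(aggregate, obs, n_layers,
                           control = em_control()) {
  stopifnot(inherits(aggregate, "aggregate_topology"),
            inherits(obs, "observation_set"),
            n_layers >= 1)
  n <- aggregate$n_nodes
  init_scale <- control$init_scale
  if (is.null(init_scale)) {
    init_scale <- max(2 * aggregate$n_edges / (n * n_layers), 1e-3)
  }
  best <- NULL
  finals <- numeric(control$restarts)
  with_seed(control$seed, {
    for (run in seq_len(control$restarts)) {
      theta <- degree_params(matrix(stats::runif(n * n_layers, 0, init_scale),
                                    n, n_layers))
      trace <- numeric(0)
      j_prev <- -Inf
      converged <- FALSE
      post <- NULL
      ne_theta <- em_nonedge_term(aggregate, theta)   # cached theta-only part
      for (it in seq_len(control$max_iter)) {
        post <- em_e_step(aggregate, obs, theta)
        j_e <- ne_theta + em_edge_term(aggregate, post, theta)
        prop <- em_m_step(post)
        ne_prop <- em_nonedge_term(aggregate, prop)
        j_m <- ne_prop + em_edge_term(aggregate, post, prop)
        shrink <- 0
        while (j_m < j_e - 1e-12 && shrink < 40) {   # generalized-EM safeguard
          prop <- degree_params((prop$d + theta$d) / 2)
          ne_prop <- em_nonedge_term(aggregate, prop)
          j_m <- ne_prop + em_edge_term(aggregate, post, prop)
          shrink <- shrink + 1
        }
        if (j_m < j_e - 1e-12) {
          prop <- theta
          ne_prop <- ne_theta
          j_m <- j_e
        }
        theta <- prop
        ne_theta <- ne_prop
        trace <- c(trace, j_m)
        if (is.finite(j_prev) && abs(j_m - j_prev) < control$tol) {
          converged <- TRUE
          break
        }
        j_prev <- j_m
      }
      post <- em_e_step(aggregate, obs, theta)   # sync Q with final theta
      finals[run] <- ne_theta + em_edge_term(aggregate, post, theta)
      if (is.null(best) || finals[run] > finals[best$run]) {
        best <- list(run = run, theta = theta, post = post, trace = trace,
                     converged = converged, n_iter = length(trace))
      }
    }
  })
  structure(
    list(
      params = best$theta,
      posterior = best$post,
      trace = best$trace,
      logJ_restarts = finals,
      best_restart = best$run,
      converged = best$converged,
      n_iter = best$n_iter
    ),
    class = "em_result"
  )
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf(
    "EM reconstruction: %d iterations (best of %d restarts), %sconverged, J = %.4f\n",
    x$n_iter, length(x$logJ_restarts), if (x$converged) "" else "NOT ",
    x$trace[length(x$trace)]))
  invisible(x)
}

#' Exact posterior by brute-force enumeration (test oracle)
#'
#' Enumerates every multiplex structure consistent with the aggregate
#' topology — all `(2^L - 1)^|A|` joint assignments of membership states to
#' aggregate edges — weighting each by the configuration-model likelihood and
#' the observation constraints, and returns the exact marginal reliabilities.
#' Complexity is exponential; the guard refuses instances beyond `max_states`
#' structures. Intended as an independent anchor for [em_e_step()].
#'
#' @param aggregate an [aggregate_topology].
#' @param obs an [observation_set].
#' @param params a [degree_params].
#' @param max_states enumeration guard (default `1e6`).
#' @return a `link_posterior` (with joint-enumeration marginals).
#' @export
enumerate_posterior <- function(aggregate, obs, params, max_states = 1e6) {
  L <- obs$n_layers
  states <- membership_states(L)
  K <- nrow(states)
  m <- aggregate$n_edges
  if (K^m > max_states) {
    stop("instance exceeds the enumeration guard", call. = FALSE)
  }
  pi_mat <- prior_matrix(params, aggregate$edges)
  O <- observed_matrix(aggregate, obs)
  # per-edge state weights and consistency, then joint enumeration
  w_edge <- matrix(1, max(m, 1), K)
  c_edge <- matrix(TRUE, max(m, 1), K)
  for (k in seq_len(K)) {
    for (a in seq_len(L)) {
      w_edge[, k] <- w_edge[, k] *
        (if (states[k, a] == 1) pi_mat[, a] else 1 - pi_mat[, a])
      o <- O[, a]
      c_edge[, k] <- c_edge[, k] & (is.na(o) | o == states[k, a])
    }
  }
  total <- 0
  marg_num <- matrix(0, m, L)
  assignment <- rep(1L, m)
  repeat {
    w <- prod(w_edge[cbind(seq_len(m), assignment)]) *
      all(c_edge[cbind(seq_len(m), assignment)])
    if (w > 0) {
      total <- total + w
      marg_num <- marg_num + w * states[assignment, , drop = FALSE]
    }
    pos <- 1L
    while (pos <= m && assignment[pos] == K) {
      assignment[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > m) break
    assignment[pos] <- assignment[pos] + 1L
  }
  if (total == 0) {
    # zero prior mass everywhere: uniform over consistent structures
    assignment <- rep(1L, m)
    repeat {
      w <- as.numeric(all(c_edge[cbind(seq_len(m), assignment)]))
      total <- total + w
      marg_num <- marg_num + w * states[assignment, , drop = FALSE]
      pos <- 1L
      while (pos <= m && assignment[pos] == K) {
        assignment[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > m) break
      assignment[pos] <- assignment[pos] + 1L
    }
  }
  structure(
    list(
      edges = aggregate$edges,
      n_nodes = aggregate$n_nodes,
      n_layers = L,
      states = states,
      state_probs = NULL,
      marginals = marg_num / total,
      observed = O,
      n_degenerate = NA_integer_
    ),
    class = "link_posterior"
  )
}
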