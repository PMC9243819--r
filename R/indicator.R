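# The entropy-based discrimination indicator.
#
# For a two-layer multiplex network the uncertainty left in the testing set
# is measured by the total information entropy H of the per-edge membership
# under a mean-field approximation; the predicted reconstruction accuracy is
# 1 - rho * H, where rho rescales H by the maximum per-edge entropy 2 ln 2
# and by how much of the uncertainty partial observations can remove.

#' Mean-field estimate of the degree ratio under partial observation
#'
#' With only a fraction `c` of entries observed, the apparent degree ratio
#' shrinks toward 1. The `simple` mode uses the empirical approximation
#' `r^c`; the `meanfield` mode uses the closed form
#' `(2r + (1-r)(1-sqrt(c))^(2/r)) / (2 - (1-r)(1-sqrt(c))^(2/r))` derived
#' from the expected per-layer mean degrees under vertex sampling. Both give
#' `r` at `c = 1` and `1` at `c = 0`.
#'
#' @param r true ratio of average degrees, in (0, 1].
#' @param c observation fraction in \[0, 1\] (vectorized).
#' @param mode `"simple"` (default) or `"meanfield"`.
#' @return the estimate `r_hat`.
#' @export
estimate_r_hat <- function(r, c, mode = c("simple", "meanfield")) {
  stopifnot(r > 0, r <= 1, all(c >= 0), all(c <= 1))
  mode <- match.arg(mode)
  if (mode == "simple") {
    r^c
  } else {
    g <- (1 - r) * (1 - sqrt(c))^(2 / r)
    (2 * r + g) / (2 - g)
  }
}

#' Mean-field estimate of the edge overlap under partial observation
#'
#' `v_hat = c * v`: with few observations the apparent overlap is small.
#'
#' @param v true Jaccard edge overlap in \[0, 1\].
#' @param c observation fraction in \[0, 1\] (vectorized).
#' @export
estimate_v_hat <- function(v, c) {
  stopifnot(v >= 0, v <= 1, all(c >= 0), all(c <= 1))
  c * v
}

#' Mean link-existence probabilities of the two layers
#'
#' Given estimates of the degree ratio and overlap, the average probability
#' that an aggregate edge belongs to layer 1 (the sparser layer) is
#' `p1 = (v_hat + r_hat)/(1 + r_hat)` and to layer 2 is
#' `p2 = (1 + v_hat r_hat)/(1 + r_hat)`; `p2 >= 1/2` always.
#'
#' @param r_hat degree-ratio estimate in (0, 1].
#' @param v_hat overlap estimate in \[0, 1\].
#' @return list with `p1` and `p2`.
#' @export
mean_link_probs <- function(r_hat, v_hat) {
  stopifnot(all(r_hat > 0), all(r_hat <= 1), all(v_hat >= 0), all(v_hat <= 1))
  list(p1 = (v_hat + r_hat) / (1 + r_hat),
       p2 = (1 + v_hat * r_hat) / (1 + r_hat))
}

# Binary entropy in nats with the 0 log 0 = 0 convention.
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log(p[ok]) - (1 - p[ok]) * log(1 - p[ok])
  h
}

#' Total information entropy of the hidden multiplex structure
#'
#' `H = -|A| * sum_a [p_a ln p_a + (1 - p_a) ln(1 - p_a)]` in nats, the
#' mean-field entropy of all `|A|` aggregate edges' memberships in the two
#' layers. Bounded by `2 ln 2 |A|`.
#'
#' @param p1,p2 mean link probabilities (see [mean_link_probs()]).
#' @param n_edges number of aggregate edges `|A|`.
#' @export
entropy_total <- function(p1, p2, n_edges) {
  n_edges * (binary_entropy(p1) + binary_entropy(p2))
}

#' Per-layer total entropies
#'
#' `H_a = -|A| * [p_a ln p_a + (1 - p_a) ln(1 - p_a)]`; `H1 >= H2` holds for
#' every valid `(r_hat, v_hat)` since `p2` is the more extreme probability.
#'
#' @inheritParams entropy_total
#' @return list with `H1`, `H2`.
#' @export
layer_entropies <- function(p1, p2, n_edges) {
  list(H1 = n_edges * binary_entropy(p1), H2 = n_edges * binary_entropy(p2))
}

#' Entropy scaling factor of the discrimination indicator
#'
#' `rho = (1 / (2 ln 2 |A|)) * (1 - ((1 - v)/(1 + v)) * c^s)`. The factor
#' `(1 - v)/(1 + v)` is the fraction of the testing-set uncertainty that
#' partial observations can remove, and `s` sets how quickly they do so as
#' `c` grows.
#'
#' @param v true edge overlap.
#' @param c observation fraction (vectorized).
#' @param s scale exponent, `s > 0`.
#' @param n_edges number of aggregate edges.
#' @export
scaling_rho <- function(v, c, s, n_edges) {
  stopifnot(s > 0)
  (1 - (1 - v) / (1 + v) * c^s) / (2 * log(2) * n_edges)
}

#' The discrimination indicator and its predicted accuracy
#'
#' Assembles the full indicator state for a two-layer multiplex network with
#' degree ratio `r`, overlap `v`, observation fraction `c`, scale exponent
#' `s` and `n_edges` aggregate edges, and predicts the reconstruction
#' accuracy as `1 - rho * H` (clamped to \[0, 1\]).
#'
#' @param r,v true degree ratio and overlap.
#' @param c observation fraction.
#' @param s scale exponent.
#' @param n_edges number of aggregate edges.
#' @param r_hat_mode passed to [estimate_r_hat()].
#' @return an `indicator_state` list: `r`, `v`, `c`, `s`, `n_edges`,
#'   `r_hat`, `v_hat`, `p1`, `p2`, `H`, `H1`, `H2`, `rho`, `rho_H`,
#'   `predicted_accuracy`, and `clamped` (whether `1 - rho H` left \[0, 1\]).
#' @examples
#' discrimination_indicator(r = 0.5, v = 0.2, c = 0.3, s = 1, n_edges = 100)
#' @export
discrimination_indicator <- function(r, v, c, s, n_edges,
                                     r_hat_mode = c("simple", "meanfield")) {
  r_hat_mode <- match.arg(r_hat_mode)
  r_hat <- estimate_r_hat(r, c, mode = r_hat_mode)
  v_hat <- estimate_v_hat(v, c)
  p <- mean_link_probs(r_hat, v_hat)
  H <- entropy_total(p$p1, p$p2, n_edges)
  Hs <- layer_entropies(p$p1, p$p2, n_edges)
  rho <- scaling_rho(v, c, s, n_edges)
  rho_H <- rho * H
  acc <- 1 - rho_H
  structure(
    list(r = r, v = v, c = c, s = s, n_edges = n_edges,
         r_hat = r_hat, v_hat = v_hat, p1 = p$p1, p2 = p$p2,
         H = H, H1 = Hs$H1, H2 = Hs$H2, rho = rho, rho_H = rho_H,
         predicted_accuracy = pmin(1, pmax(0, acc)),
         clamped = any(acc < 0 | acc > 1)),
    class = "indicator_state"
  )
}

#' Predicted reconstruction accuracy from an indicator state
#'
#' @param state an `indicator_state` from [discrimination_indicator()].
#' @return `1 - rho * H`, clamped to \[0, 1\].
#' @export
predict_accuracy <- function(state) {
  stopifnot(inherits(state, "indicator_state"))
  state$predicted_accuracy
}

#' @export
print.indicator_state <- function(x, ...) {
  cat(sprintf(
    "Discrimination indicator: r = %.3g, v = %.3g, c = %.3g, s = %.3g, |A| = %d\n",
    x$r, x$v, x$c[1], x$s, x$n_edges))
  cat(sprintf("  r_hat = %.4g, v_hat = %.4g, H = %.4g nats, rho*H = %.4g\n",
              x$r_hat[1], x$v_hat[1], x$H[1], x$rho_H[1]))
  cat(sprintf("  predicted accuracy = %.4g\n", x$predicted_accuracy[1]))
  invisible(x)
}

#' Fit the scale exponent s from a measured accuracy curve
#'
#' Least-squares fit of `s` in `accuracy(c) = 1 - rho(c; s) * H(c)` against
#' measured accuracies at several observation fractions, minimized over
#' `s` in (0, 10\] with a log-spaced multistart followed by local refinement.
#' The `"cosine"` method instead returns `kappa * cosine`, using the
#' empirical proportionality between `s` and the cosine similarity of the
#' two layers' degree sequences.
#'
#' @param curve data frame with columns `c` and `accuracy` (at least three
#'   distinct `c` in (0, 1) for the least-squares method).
#' @param v,r true overlap and degree ratio of the network.
#' @param n_edges number of aggregate edges.
#' @param method `"ls"` (default) or `"cosine"`.
#' @param cosine degree-sequence cosine similarity (cosine method).
#' @param kappa proportionality constant for the cosine method (default 1).
#' @param r_hat_mode passed to [estimate_r_hat()].
#' @return the fitted `s`.
#' @export
fit_s <- function(curve = NULL, v = NULL, r = NULL, n_edges = NULL,
                  method = c("ls", "cosine"), cosine = NULL, kappa = 1,
                  r_hat_mode = c("simple", "meanfield")) {
  method <- match.arg(method)
  if (method == "cosine") {
    if (is.null(cosine)) stop("cosine method needs `cosine`", call. = FALSE)
    return(kappa * cosine)
  }
  r_hat_mode <- match.arg(r_hat_mode)
  stopifnot(is.data.frame(curve), all(c("c", "accuracy") %in% names(curve)))
  cc <- curve$c
  acc <- curve$accuracy
  if (sum(cc > 0 & cc < 1) < 3 || length(unique(cc)) < 3) {
    stop("need at least three curve points with distinct c in (0, 1)",
         call. = FALSE)
  }
  if (stats::var(acc) == 0) {
    stop("degenerate accuracy curve: constant accuracy", call. = FALSE)
  }
  predict_at <- function(s) {
    vapply(cc, function(ci) {
      st <- discrimination_indicator(r, v, ci, s, n_edges,
                                     r_hat_mode = r_hat_mode)
      st$predicted_accuracy
    }, numeric(1))
  }
  obj <- function(s) sum((acc - predict_at(s))^2)
  grid <- exp(seq(log(0.01), log(10), length.out = 40))
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  stats::optimize(obj, lower = lo, upper = hi, tol = 1e-9)$minimum
}
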