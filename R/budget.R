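# Budget allocation between the layers of a two-layer multiplex network.
#
# When the two layers may be observed at different fractions c1, c2 with a
# fixed mean budget cbar = (c1 + c2)/2, the predicted accuracy becomes the
# two-argument surface
#   F(c1, c2) = 1 - w1 rho1 H1 - w2 rho2 H2,
#   w1 = (1 - c1) / ((1 - c1) + (1 - c2)/r_hat),  w2 = 1 - w1,
#   rho_a = (1/(2 ln 2 |A|)) (1 - ((1 - v)/(1 + v)) c_{3-a}^s),
# with H1 >= H2 the per-layer total entropies (layer 1 is the sparser one).

#' Define a budget-allocation problem
#'
#' @param c_bar mean observation fraction, `0 <= c_bar < 1`.
#' @param v edge overlap.
#' @param s scale exponent.
#' @param n_edges number of aggregate edges.
#' @param r_hat degree-ratio estimate in (0, 1].
#' @param H1,H2 per-layer total entropies in nats (scaled by `n_edges`;
#'   see [layer_entropies()]); `H1 >= H2` is required — order the layers so
#'   that layer 1 is the sparser (higher-entropy) one.
#' @return a `budget_problem` list.
#' @export
budget_problem <- function(c_bar, v, s, n_edges, r_hat, H1, H2) {
  stopifnot(c_bar >= 0, c_bar < 1, s > 0, r_hat > 0, r_hat <= 1)
  if (H1 < H2) {
    stop("H1 < H2: order the layers so the sparser (higher-entropy) layer is layer 1",
         call. = FALSE)
  }
  structure(list(c_bar = c_bar, v = v, s = s, n_edges = n_edges,
                 r_hat = r_hat, H1 = H1, H2 = H2),
            class = "budget_problem")
}

#' Predicted-accuracy surface over per-layer observation fractions
#'
#' Evaluates `F(c1, c2)` (vectorized over `c1`, `c2`). The 0/0 weight at
#' `c1 = c2 = 1` is resolved by its limit `w1 = r_hat / (1 + r_hat)`.
#' Values are clamped to \[0, 1\] like [predict_accuracy()].
#'
#' @param problem a [budget_problem].
#' @param c1,c2 per-layer observation fractions in \[0, 1\].
#' @export
budget_accuracy <- function(problem, c1, c2) {
  stopifnot(inherits(problem, "budget_problem"),
            all(c1 >= 0 & c1 <= 1), all(c2 >= 0 & c2 <= 1))
  p <- problem
  denom <- (1 - c1) + (1 - c2) / p$r_hat
  w1 <- ifelse(denom > 0, (1 - c1) / denom, p$r_hat / (1 + p$r_hat))
  rho1 <- scaling_rho(p$v, c2, p$s, p$n_edges)
  rho2 <- scaling_rho(p$v, c1, p$s, p$n_edges)
  f <- 1 - w1 * rho1 * p$H1 - (1 - w1) * rho2 * p$H2
  pmin(1, pmax(0, f))
}

#' Accuracy along a fixed budget line
#'
#' With the mean budget fixed at `c_bar`, `c2 = 2 c_bar - c1` and `F`
#' becomes a function of `c1` alone on the domain `[0, 2 c_bar]` when
#' `c_bar <= 1/2` and `[2 c_bar - 1, 1]` otherwise.
#'
#' @param problem a [budget_problem].
#' @param c1 layer-1 fractions within the domain (vectorized).
#' @export
budget_accuracy_restricted <- function(problem, c1) {
  dom <- budget_domain(problem$c_bar)
  if (any(c1 < dom[1] - 1e-12 | c1 > dom[2] + 1e-12)) {
    stop(sprintf("c1 outside the budget domain [%.4g, %.4g]", dom[1], dom[2]),
         call. = FALSE)
  }
  c1 <- pmin(pmax(c1, dom[1]), dom[2])
  budget_accuracy(problem, c1, 2 * problem$c_bar - c1)
}

budget_domain <- function(c_bar) {
  if (c_bar <= 0.5) c(0, 2 * c_bar) else c(2 * c_bar - 1, 1)
}

#' Budget threshold where extreme allocations tie
#'
#' Solves `F(0; c_bar) = F(2 c_bar; c_bar)` for `c_bar` on (0, 1/2] by
#' bisection after a sign-change scan. Below the threshold only the
#' all-to-one-layer extreme is optimal; above it both extremes beat balanced
#' allocation. When the difference never changes sign on the interval no
#' root is reported (rather than fabricating one).
#'
#' @param problem a [budget_problem] (its `c_bar` field is ignored here).
#' @param lower,upper search interval, default (1e-4, 0.5\].
#' @param tol absolute root tolerance.
#' @return list with `c_bar0` (`NA` if absent), `found`, and `residual`
#'   (`F(0) - F(2 c_bar0)` at the root).
#' @export
budget_threshold <- function(problem, lower = 1e-4, upper = 0.5, tol = 1e-6) {
  stopifnot(inherits(problem, "budget_problem"))
  gap <- function(cb) {
    pr <- problem
    pr$c_bar <- cb
    budget_accuracy(pr, 0, 2 * cb) - budget_accuracy(pr, 2 * cb, 0)
  }
  grid <- seq(lower, upper, length.out = 201)
  g <- vapply(grid, gap, numeric(1))
  flip <- which(g[-length(g)] * g[-1] < 0)
  if (length(flip) == 0) {
    exact <- which(g == 0)
    if (length(exact) > 0) {
      return(list(c_bar0 = grid[exact[1]], found = TRUE, residual = 0))
    }
    return(list(c_bar0 = NA_real_, found = FALSE, residual = NA_real_))
  }
  root <- stats::uniroot(gap, lower = grid[flip[1]], upper = grid[flip[1] + 1],
                         tol = tol)$root
  list(c_bar0 = root, found = TRUE, residual = gap(root))
}

#' Recommend how to split a fixed observation budget
#'
#' Maximizes `F` along the budget line over a fine grid plus the domain
#' endpoints. The maximum sits at the endpoint that loads the sparser layer
#' (`c1 = 2 c_bar` when `c_bar <= 1/2`, else `c1 = 1`), consistent with the
#' boundary inequalities `F(0) <= F(2 c_bar)` and `F(2 c_bar - 1) <= F(1)`.
#'
#' @param problem a [budget_problem].
#' @param grid_size number of interior grid points evaluated.
#' @return list with `c1`, `c2`, `accuracy`, and a `rationale` string naming
#'   the regime (`c_bar` below or above the threshold of
#'   [budget_threshold()]).
#' @export
budget_recommend <- function(problem, grid_size = 201) {
  dom <- budget_domain(problem$c_bar)
  c1 <- seq(dom[1], dom[2], length.out = grid_size)
  f <- budget_accuracy_restricted(problem, c1)
  best <- which.max(f)
  if (best > 1 && best < grid_size && dom[2] > dom[1]) {
    # refine an interior grid maximum locally
    opt <- stats::optimize(function(x) budget_accuracy_restricted(problem, x),
                           lower = c1[best - 1], upper = c1[best + 1],
                           maximum = TRUE, tol = 1e-10)
    if (opt$objective > f[best]) {
      c1 <- c(c1, opt$maximum)
      f <- c(f, opt$objective)
      best <- length(f)
    }
  }
  thr <- budget_threshold(problem)
  regime <- if (!thr$found) {
    "no interior threshold on (0, 1/2]"
  } else if (problem$c_bar <= thr$c_bar0) {
    sprintf("c_bar = %.3g <= c_bar0 = %.3g: only the sparser-layer extreme is optimal",
            problem$c_bar, thr$c_bar0)
  } else {
    sprintf("c_bar = %.3g > c_bar0 = %.3g: both extremes beat balanced allocation",
            problem$c_bar, thr$c_bar0)
  }
  list(
    c1 = c1[best],
    c2 = 2 * problem$c_bar - c1[best],
    accuracy = f[best],
    rationale = paste0(
      "allocate the budget as much as possible to the sparser layer; ", regime)
  )
}
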