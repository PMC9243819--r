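#' Measure a reconstruction accuracy-vs-c curve
#'
#' For each observation fraction, samples partial observations of the ground
#' truth, reconstructs with [reconstruct_em()], and measures the testing-set
#' accuracy at threshold `q`. The default sampling draws independent
#' per-layer vertex samples at `c1 = c2 = c`, so that a testing-set entry can
#' have an observed counterpart in the other layer — the mechanism through
#' which partial observations reduce testing-set uncertainty; `"vertex"`
#' uses a single shared node set instead.
#'
#' @param m the ground-truth two-layer [multiplex_network].
#' @param c_values observation fractions to sweep.
#' @param n_seeds observation resamples per fraction.
#' @param control an [em_control] for the reconstructions.
#' @param q classification threshold (default 0.5).
#' @param sampling `"per_layer"` (default) or `"vertex"`.
#' @param seed base seed; each (c, replicate) derives its own sub-seed.
#' @return data frame with columns `c`, `replicate`, `accuracy`,
#'   `realized_c`.
#' @export
measure_accuracy_curve <- function(m, c_values, n_seeds = 1,
                                   control = em_control(restarts = 1,
                                                        tol = 1e-5,
                                                        max_iter = 40),
                                   q = 0.5,
                                   sampling = c("per_layer", "vertex"),
                                   seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(m, "multiplex_network"))
  agg <- aggregate_or(m)
  out <- list()
  for (ci in seq_along(c_values)) {
    cc <- c_values[ci]
    for (rep in seq_len(n_seeds)) {
      sub <- (seed * 2654435L + ci * 97003L + rep * 101L) %% 2100000000L
      g <- if (sampling == "per_layer") {
        sample_observations_budget(m, cc, cc, seed = sub)
      } else {
        sample_observations_vertex(m, cc, seed = sub)
      }
      ts <- build_test_set(agg, g, m$n_layers)
      if (ts$n_items == 0) {
        out[[length(out) + 1]] <- data.frame(
          c = cc, replicate = rep, accuracy = 1, realized_c = g$c)
        next
      }
      ctrl <- control
      ctrl$seed <- sub + 1L
      fit <- reconstruct_em(agg, g, m$n_layers, ctrl)
      acc <- summary_metrics(confusion_counts(fit$posterior, m, ts, q))$accuracy
      out[[length(out) + 1]] <- data.frame(
        c = cc, replicate = rep, accuracy = acc, realized_c = g$c)
    }
  }
  do.call(rbind, out)
}

#' Sweep network characteristics and compare measured accuracy with the
#' discrimination indicator
#'
#' For every (r, v) cell with `v <= r`, generates replicate two-layer
#' networks with the Erdős–Rényi pair generator, measures the reconstruction
#' accuracy over the observation fractions, fits the scale exponent `s` to
#' the cell's mean accuracy curve, and evaluates the predicted accuracy
#' `1 - rho H`. The Pearson correlation between the `accuracy` and
#' `predicted` columns summarizes how well the indicator anticipates the
#' reconstruction.
#'
#' @param r_values,v_values grids of the degree ratio and overlap (cells
#'   with `v > r` are skipped).
#' @param c_values observation fractions.
#' @param n_seeds replicate networks per cell.
#' @param n_nodes network size.
#' @param control an [em_control] for the reconstructions.
#' @param seed base seed.
#' @return data frame with one row per (cell, c): `r`, `v` (cell targets),
#'   `c`, `accuracy` (mean over replicates), `predicted`, `s`.
#' @export
indicator_accuracy_sweep <- function(r_values, v_values, c_values,
                                     n_seeds = 2, n_nodes = 500,
                                     control = em_control(restarts = 1,
                                                          tol = 1e-5,
                                                          max_iter = 30),
                                     seed = 1) {
  rows <- list()
  cell <- 0
  for (r in r_values) for (v in v_values[v_values <= r]) {
    cell <- cell + 1
    acc <- matrix(NA_real_, n_seeds, length(c_values))
    rs <- vs <- ms <- numeric(n_seeds)
    for (k in seq_len(n_seeds)) {
      net_seed <- (seed * 1117 + cell * 211 + k * 17) %% 2100000000
      m <- generate_er_pair(n_nodes, r, v, seed = net_seed)
      ch <- characterize_multiplex(m)
      rs[k] <- ch$r; vs[k] <- ch$v
      ms[k] <- aggregate_or(m)$n_edges
      curve <- measure_accuracy_curve(m, c_values, n_seeds = 1,
                                      control = control,
                                      seed = net_seed + 1)
      acc[k, ] <- curve$accuracy
    }
    mean_acc <- colMeans(acc)
    r_bar <- mean(rs); v_bar <- mean(vs); m_bar <- mean(ms)
    s_hat <- tryCatch(
      fit_s(data.frame(c = c_values, accuracy = mean_acc),
            v = v_bar, r = r_bar, n_edges = m_bar),
      error = function(e) NA_real_)
    pred <- if (is.na(s_hat)) rep(NA_real_, length(c_values)) else {
      vapply(c_values, function(cc) {
        discrimination_indicator(r_bar, v_bar, cc, s_hat,
                                 m_bar)$predicted_accuracy
      }, numeric(1))
    }
    rows[[cell]] <- data.frame(r = r, v = v, c = c_values,
                               accuracy = mean_acc, predicted = pred,
                               s = s_hat)
  }
  do.call(rbind, rows)
}

#' Sweep degree-sequence cosine similarity and fit the scale exponent
#'
#' Generates networks from degree-sequence pairs spanning the requested
#' cosine similarities, measures each network's accuracy-vs-c curve, fits
#' `s`, and returns one row per network. The Pearson correlation between
#' `s` and `cosine` summarizes the proportionality between the scale
#' exponent and the mesoscale similarity of the layers.
#'
#' @param cosine_targets cosine similarities to span.
#' @param c_values observation fractions for the accuracy curves.
#' @param n_seeds replicate networks per target.
#' @param n_nodes network size.
#' @param control an [em_control].
#' @param seed base seed.
#' @return data frame with `target`, `cosine` (realized), `r`, `v`, `s`.
#' @export
s_cosine_sweep <- function(cosine_targets, c_values,
                           n_seeds = 3, n_nodes = 500,
                           control = em_control(restarts = 1, tol = 1e-5,
                                                max_iter = 30),
                           seed = 1) {
  rows <- list()
  idx <- 0
  for (ct in cosine_targets) for (k in seq_len(n_seeds)) {
    idx <- idx + 1
    net_seed <- (seed * 3301 + idx * 419) %% 2100000000
    ds <- make_degree_sequences(n_nodes, ct, seed = net_seed)
    m <- generate_from_degree_sequences(ds$d1, ds$d2, seed = net_seed + 1)
    ch <- characterize_multiplex(m)
    agg <- aggregate_or(m)
    curve <- measure_accuracy_curve(m, c_values, n_seeds = 1,
                                    control = control, seed = net_seed + 2)
    s_hat <- tryCatch(
      fit_s(data.frame(c = c_values, accuracy = curve$accuracy),
            v = ch$v, r = ch$r, n_edges = agg$n_edges),
      error = function(e) NA_real_)
    rows[[idx]] <- data.frame(target = ct, cosine = ch$cosine,
                              r = ch$r, v = ch$v, s = s_hat)
  }
  do.call(rbind, rows)
}
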