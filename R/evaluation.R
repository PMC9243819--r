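# Reconstruction quality metrics over the testing set.

# Reliability and truth lookups for the items of a test set.
test_scores <- function(posterior, truth, test_set) {
  stopifnot(inherits(posterior, "link_posterior"),
            inherits(truth, "multiplex_network"),
            inherits(test_set, "test_set"))
  items <- test_set$items
  n <- posterior$n_nodes
  edge_key <- pair_key(posterior$edges[, 1], posterior$edges[, 2], n)
  row <- match(pair_key(items$i, items$j, n), edge_key)
  if (anyNA(row)) {
    stop("a testing-set entry has no reliability in the posterior", call. = FALSE)
  }
  score <- posterior$marginals[cbind(row, items$layer)]
  label <- logical(nrow(items))
  for (a in unique(items$layer)) {
    e <- truth$layers[[a]]
    keys <- pair_key(e[, 1], e[, 2], n)
    sel <- items$layer == a
    label[sel] <- pair_key(items$i[sel], items$j[sel], n) %in% keys
  }
  list(score = score, label = as.integer(label))
}

#' Confusion counts with the half-contribution tie rule
#'
#' Entries with reliability above the threshold `q` count as predicted
#' positive, below as predicted negative; entries exactly at `q` contribute
#' one half to each side of their truth row, so counts can be half-integers
#' but always sum to the testing-set size.
#'
#' @param posterior a `link_posterior`.
#' @param truth the ground-truth [multiplex_network].
#' @param test_set a [build_test_set()] result.
#' @param q threshold in (0, 1), default 0.5.
#' @return list with `tp`, `fp`, `tn`, `fn`, `q`, `n_items`.
#' @export
confusion_counts <- function(posterior, truth, test_set, q = 0.5) {
  stopifnot(q > 0, q < 1)
  sc <- test_scores(posterior, truth, test_set)
  pos <- sc$label == 1
  above <- sc$score > q
  below <- sc$score < q
  at <- sc$score == q
  list(
    tp = sum(above & pos) + 0.5 * sum(at & pos),
    fp = sum(above & !pos) + 0.5 * sum(at & !pos),
    tn = sum(below & !pos) + 0.5 * sum(at & !pos),
    fn = sum(below & pos) + 0.5 * sum(at & pos),
    q = q,
    n_items = length(sc$score)
  )
}

#' Threshold metrics from confusion counts
#'
#' Standard accuracy, precision, recall and Matthews correlation
#' coefficient. Ratios with a zero denominator are reported as `NA` rather
#' than coerced to 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return list with `accuracy`, `precision`, `recall`, `mcc` plus the
#'   counts.
#' @export
summary_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = safe(tp + tn, total),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn, q = counts$q, n_items = counts$n_items
  )
}

#' Threshold-free ranking metrics: AUC and AUPRC
#'
#' AUC is the probability that a true link receives a higher reliability
#' than a non-link, computed by the rank (Mann–Whitney) formulation with
#' ties counting one half. AUPRC integrates precision over recall
#' increments, grouping tied scores.
#'
#' @inheritParams confusion_counts
#' @return list with `auc`, `auprc`, `n_pos`, `n_neg`.
#' @export
rank_metrics <- function(posterior, truth, test_set) {
  sc <- test_scores(posterior, truth, test_set)
  n_pos <- sum(sc$label == 1)
  n_neg <- sum(sc$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop(sprintf("testing set contains no %s entries: AUC undefined",
                 if (n_pos == 0) "positive" else "negative"), call. = FALSE)
  }
  rk <- rank(sc$score)   # average ranks implement the 1/2 tie convention
  auc <- (sum(rk[sc$label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # precision-recall curve over distinct thresholds, descending
  ord <- order(sc$score, decreasing = TRUE)
  s <- sc$score[ord]
  y <- sc$label[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  last <- which(diff(s) != 0)      # last index of each tied score block
  last <- c(last, length(s))
  prec <- cum_tp[last] / (cum_tp[last] + cum_fp[last])
  rec <- cum_tp[last] / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, auprc = auprc, n_pos = n_pos, n_neg = n_neg)
}

#' Full evaluation report for a reconstruction
#'
#' @inheritParams confusion_counts
#' @return an `eval_report` combining [summary_metrics()] and, when both
#'   classes are present, [rank_metrics()] (`NA` otherwise).
#' @export
evaluate_reconstruction <- function(posterior, truth, test_set, q = 0.5) {
  out <- summary_metrics(confusion_counts(posterior, truth, test_set, q))
  rk <- tryCatch(rank_metrics(posterior, truth, test_set),
                 error = function(e) list(auc = NA_real_, auprc = NA_real_))
  out$auc <- rk$auc
  out$auprc <- rk$auprc
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d test entries (q = %.2f):\n", x$n_items, x$q))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  MCC %.4f\n",
              x$accuracy, x$precision, x$recall, x$mcc))
  cat(sprintf("  AUC %.4f  AUPRC %.4f\n", x$auc, x$auprc))
  invisible(x)
}
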