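# Readers and writers for the plain-text interchange formats:
#   multilayer edge list:  layer_id node_i node_j [weight]   (# comments)
#   aggregate edge list:   node_i node_j
#   observation file:      node_i node_j layer_id value
#   reliability table:     node_i node_j layer Q   (tab-separated)
# Layers are 1-based in files; arbitrary node labels are mapped to internal
# indices 1..N and the mapping is preserved on output.

read_token_table <- function(path, n_cols_min) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(rows, length, 1L) < n_cols_min)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: expected at least %d fields",
                 keep[bad[1]], path, n_cols_min), call. = FALSE)
  }
  rows
}

# Sort labels numerically when they all parse as numbers, else
# lexicographically; gives a deterministic internal index assignment.
label_map <- function(labels) {
  u <- unique(labels)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Read a multilayer edge list
#'
#' Whitespace-separated records `layer_id node_i node_j [weight]`, one per
#' line, `#` comments allowed; weights are ignored (presence is binarized)
#' and both orientations of a pair are merged.
#'
#' @param path file path.
#' @param n_layers optional number of layers `L`; defaults to the largest
#'   layer id present. Ids outside `1..L` are an error.
#' @param n_nodes optional node count (to include isolated trailing nodes).
#' @return a [multiplex_network] with the label map in `$labels`.
#' @export
read_multiplex <- function(path, n_layers = NULL, n_nodes = NULL) {
  rows <- read_token_table(path, 3)
  if (length(rows) == 0) {
    return(multiplex_network(rep(list(NULL), max(1, n_layers %||% 1)),
                             n_nodes %||% 1))
  }
  lay <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1)))
  if (anyNA(lay)) stop("non-integer layer id in ", path, call. = FALSE)
  L <- n_layers %||% max(lay)
  if (any(lay < 1L | lay > L)) {
    stop(sprintf("layer id outside 1..%d in %s", L, path), call. = FALSE)
  }
  a <- vapply(rows, `[`, "", 2)
  b <- vapply(rows, `[`, "", 3)
  labels <- label_map(c(a, b))
  n <- n_nodes %||% length(labels)
  ia <- match(a, labels)
  ib <- match(b, labels)
  layers <- lapply(seq_len(L), function(k) {
    cbind(ia[lay == k], ib[lay == k])
  })
  multiplex_network(layers, n, labels = labels)
}

#' Write a multilayer edge list
#'
#' @param m a [multiplex_network].
#' @param path output path.
#' @export
write_multiplex <- function(m, path) {
  stopifnot(inherits(m, "multiplex_network"))
  lab <- m$labels %||% as.character(seq_len(m$n_nodes))
  con <- file(path, "w")
  on.exit(close(con))
  for (a in seq_len(m$n_layers)) {
    e <- m$layers[[a]]
    if (nrow(e) > 0) {
      writeLines(paste(a, lab[e[, 1]], lab[e[, 2]]), con)
    }
  }
  invisible(path)
}

#' Read an aggregate edge list (`node_i node_j` per line)
#'
#' @param path file path.
#' @param labels optional label vector fixing the index mapping (e.g. from a
#'   companion [read_multiplex()] network); inferred from the file otherwise.
#' @return an [aggregate_topology].
#' @export
read_aggregate <- function(path, labels = NULL) {
  rows <- read_token_table(path, 2)
  if (length(rows) == 0) return(aggregate_topology(NULL, length(labels) %||% 1))
  a <- vapply(rows, `[`, "", 1)
  b <- vapply(rows, `[`, "", 2)
  labels <- labels %||% label_map(c(a, b))
  agg <- aggregate_topology(cbind(match(a, labels), match(b, labels)),
                            length(labels))
  agg$labels <- labels
  agg
}

#' Read an observation file (`node_i node_j layer_id value` per line)
#'
#' @param path file path.
#' @param aggregate the companion [aggregate_topology].
#' @param n_layers number of layers.
#' @param labels optional label vector fixing the index mapping.
#' @return an [observation_set].
#' @export
read_observations <- function(path, aggregate, n_layers, labels = NULL) {
  rows <- read_token_table(path, 4)
  if (length(rows) == 0) {
    return(observation_set(NULL, aggregate, n_layers))
  }
  a <- vapply(rows, `[`, "", 1)
  b <- vapply(rows, `[`, "", 2)
  if (is.null(labels)) {
    num <- suppressWarnings(cbind(as.integer(a), as.integer(b)))
    if (anyNA(num)) stop("labelled observation files need `labels`", call. = FALSE)
    ia <- num[, 1]; ib <- num[, 2]
  } else {
    ia <- match(a, labels); ib <- match(b, labels)
  }
  observation_set(
    data.frame(i = ia, j = ib,
               layer = as.integer(vapply(rows, `[`, "", 3)),
               value = as.integer(vapply(rows, `[`, "", 4))),
    aggregate, n_layers)
}

#' Write an observation file
#'
#' @param obs an [observation_set].
#' @param path output path.
#' @param labels optional label vector mapping indices back to labels.
#' @export
write_observations <- function(obs, path, labels = NULL) {
  e <- obs$entries
  lab <- function(x) if (is.null(labels)) x else labels[x]
  writeLines(paste(lab(e$i), lab(e$j), e$layer, e$value), path)
  invisible(path)
}

#' Write link reliabilities as a TSV
#'
#' Columns `node_i node_j layer Q` with 10 significant digits, rows ordered
#' by pair (`i < j`) then layer — byte-stable across runs for identical
#' posteriors.
#'
#' @param posterior a `link_posterior`.
#' @param path output path.
#' @param labels optional label vector.
#' @export
write_reliabilities <- function(posterior, path, labels = NULL) {
  stopifnot(inherits(posterior, "link_posterior"))
  e <- posterior$edges
  L <- posterior$n_layers
  lab <- function(x) if (is.null(labels)) x else labels[x]
  lines <- paste(
    lab(rep(e[, 1], each = L)),
    lab(rep(e[, 2], each = L)),
    rep(seq_len(L), times = nrow(e)),
    sprintf("%.10g", as.vector(t(posterior$marginals))),
    sep = "\t")
  writeLines(c("node_i\tnode_j\tlayer\tQ", lines), path)
  invisible(path)
}

#' Read a reliability TSV written by [write_reliabilities()]
#'
#' @param path file path.
#' @return data frame with columns `node_i`, `node_j`, `layer`, `Q`.
#' @export
read_reliabilities <- function(path) {
  utils::read.delim(path, header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "numeric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
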