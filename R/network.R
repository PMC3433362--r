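#' Lagged parent set
#'
#' A parent set for one child gene: each member is a (gene, lag) pair, lag
#' counted in time slices (`lag = 1` means regulation from the previous
#' slice).  Duplicate (gene, lag) pairs are not allowed; the empty set is the
#' valid "no regulators" model.
#'
#' @param gene integer vector of regulator gene indices (may be empty).
#' @param lag integer vector of lags, same length as `gene`, all `>= 1`.
#' @return a data frame of class `lagged_parents` with columns `gene`, `lag`.
#' @export
lagged_parents <- function(gene = integer(0), lag = integer(0)) {
  gene <- as.integer(gene)
  lag <- as.integer(lag)
  if (length(gene) != length(lag))
    stop_invalid("`gene` and `lag` must have the same length")
  if (length(lag) > 0L && any(lag < 1L))
    stop_invalid("lags must be >= 1 (inter-slice edges only)")
  df <- data.frame(gene = gene, lag = lag)
  if (anyDuplicated(df)) stop_invalid("duplicate (gene, lag) pair")
  class(df) <- c("lagged_parents", "data.frame")
  df
}

as_lagged_parents <- function(x, dataset = NULL) {
  if (is.null(x)) return(lagged_parents())
  if (inherits(x, "lagged_parents")) {
    df <- x
  } else if (is.data.frame(x)) {
    df <- lagged_parents(x$gene, x$lag)
  } else {
    stop_invalid("`parents` must be a lagged_parents object or data frame")
  }
  if (!is.null(dataset) && nrow(df) > 0L &&
      (any(df$gene < 1L) || any(df$gene > dataset$n)))
    stop_invalid("parent gene index out of range")
  df
}

#' Transition network of a d-th order dynamic Bayesian network
#'
#' One lagged parent set per gene.  Because only inter-time-slice edges are
#' modeled, acyclicity holds by construction and is never checked;
#' self-regulation at lag `>= 1` is permitted.
#'
#' @param parent_sets list with one [lagged_parents()] entry per gene.
#' @param d Markov order; all lags must lie in `1..d`.
#' @param gene_ids character vector of gene identifiers.
#' @return an object of class `dbn_network`.
#' @export
dbn_network <- function(parent_sets, d, gene_ids) {
  d <- as.integer(d)
  gene_ids <- as.character(gene_ids)
  if (length(parent_sets) != length(gene_ids))
    stop_invalid("one parent set per gene required")
  parent_sets <- lapply(parent_sets, as_lagged_parents)
  for (ps in parent_sets) {
    if (nrow(ps) > 0L && any(ps$lag > d))
      stop_invalid("invalid network: lag exceeds order d")
    if (nrow(ps) > 0L && (any(ps$gene < 1L) || any(ps$gene > length(gene_ids))))
      stop_invalid("invalid network: gene index out of range")
  }
  names(parent_sets) <- gene_ids
  structure(list(parent_sets = parent_sets, d = d, gene_ids = gene_ids),
            class = "dbn_network")
}

#' Edge list of a network
#'
#' @param network a [dbn_network()] or a truth network.
#' @return data frame with columns `regulator`, `target`, `lag` (gene ids)
#'   and, when available from learning, `delta_mi` (the mutual-information
#'   gain contributed by the parent when added last).
#' @export
as_edge_list <- function(network) {
  if (inherits(network, "truth_network")) {
    df <- as.data.frame(network)[, c("regulator", "target", "lag")]
    rownames(df) <- NULL
    return(df)
  }
  stopifnot(inherits(network, "dbn_network"))
  rows <- lapply(seq_along(network$parent_sets), function(i) {
    ps <- network$parent_sets[[i]]
    if (nrow(ps) == 0L) return(NULL)
    out <- data.frame(regulator = network$gene_ids[ps$gene],
                      target = network$gene_ids[i],
                      lag = ps$lag)
    out$delta_mi <- if (!is.null(ps$delta_mi)) ps$delta_mi else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(regulator = character(0), target = character(0),
                      lag = integer(0), delta_mi = numeric(0))
  rownames(out) <- NULL
  out
}

#' @export
print.dbn_network <- function(x, ...) {
  el <- as_edge_list(x)
  cat(sprintf("<dbn_network> order d = %d, %d genes, %d edges\n",
              x$d, length(x$gene_ids), nrow(el)))
  invisible(x)
}

#' Ground-truth lagged network
#'
#' Truth networks carry (regulator, target, lag) triples and, for the leveled
#' cascade benchmarks, a node -> level map.  When levels are present every
#' edge must run from a shallower to a deeper level with lag equal to the
#' level gap (the construction that turns a static cascade into a lagged
#' one by shifting level-l profiles forward by l - 1 time units).
#'
#' @param nodes character vector of gene ids.
#' @param edges data frame with columns `regulator`, `target`, `lag`.
#' @param levels optional named integer vector (node -> level in `1..L`).
#' @param surrogate logical flag recording that a packaged topology is a
#'   documented stand-in rather than a published wiring.
#' @return a data frame of class `truth_network` with attributes `nodes`,
#'   `levels`, `surrogate`.
#' @export
truth_network <- function(nodes, edges, levels = NULL, surrogate = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_invalid("duplicate node ids")
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      lag = as.integer(edges$lag))
  if (nrow(edges) > 0L) {
    if (any(edges$lag < 1L)) stop_invalid("edge lags must be >= 1")
    if (!all(edges$regulator %in% nodes) || !all(edges$target %in% nodes))
      stop_invalid("edge endpoints must be listed nodes")
    if (anyDuplicated(edges)) stop_invalid("duplicate (regulator, target, lag)")
  }
  if (!is.null(levels)) {
    levels <- stats::setNames(as.integer(levels), names(levels))
    if (!all(nodes %in% names(levels)))
      stop_invalid("levels must cover every node")
    gap <- levels[edges$target] - levels[edges$regulator]
    if (nrow(edges) > 0L && any(gap != edges$lag))
      stop_invalid("leveled network: lag must equal the level gap")
  }
  structure(edges, class = c("truth_network", "data.frame"),
            nodes = nodes, levels = levels, surrogate = isTRUE(surrogate))
}

#' @export
print.truth_network <- function(x, ...) {
  lv <- attr(x, "levels")
  cat(sprintf("<truth_network> %d nodes, %d edges%s%s\n",
              length(attr(x, "nodes")), nrow(x),
              if (!is.null(lv)) sprintf(", %d levels", max(lv)) else "",
              if (isTRUE(attr(x, "surrogate"))) " (surrogate topology)" else ""))
  if (nrow(x) > 0L) {
    tab <- table(x$lag)
    cat("  edges by order: ",
        paste(sprintf("lag %s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
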