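#' Multi-series time-course expression data
#'
#' A `time_series_set` holds one or more real-valued expression matrices over
#' the same genes: rows are genes, columns are time points.  Several series
#' arise from replicate experiments or independent time courses; all scoring
#' machinery keeps them separate so that no aligned sample ever pairs
#' observations from two different series.
#'
#' @param series a matrix, or a list of matrices, each `n` genes x `Ni` time
#'   points with `Ni >= 2`.  All matrices must have the same number of rows in
#'   the same gene order.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the rownames of the first series or `g1..gn`.
#' @return an object of class `time_series_set` with fields `series` (list of
#'   matrices), `gene_ids`, `n` (genes) and `m` (number of series).
#' @examples
#' tss <- time_series_set(matrix(rnorm(20), 4, 5))
#' tss$m
#' @export
time_series_set <- function(series, gene_ids = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (!is.list(series) || length(series) == 0L)
    stop_invalid("`series` must be a matrix or a non-empty list of matrices")
  series <- lapply(series, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  n <- nrow(series[[1L]])
  if (n < 1L) stop_invalid("need at least one gene")
  for (s in series) {
    if (nrow(s) != n) stop_invalid("all series must have the same gene set")
    if (ncol(s) < 2L) stop_invalid("every series needs at least 2 time points")
    if (!all(is.finite(s))) stop_invalid("expression values must be finite")
  }
  if (is.null(gene_ids)) gene_ids <- rownames(series[[1L]])
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n || anyDuplicated(gene_ids))
    stop_invalid("`gene_ids` must be unique and match the number of rows")
  series <- lapply(series, function(s) {
    rownames(s) <- gene_ids
    s
  })
  structure(list(series = series, gene_ids = gene_ids, n = n,
                 m = length(series)),
            class = "time_series_set")
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("<time_series_set> %d genes, %d series (lengths: %s)\n",
              x$n, x$m, paste(vapply(x$series, ncol, 1L), collapse = ", ")))
  invisible(x)
}

#' Discrete expression data with a uniform number of states
#'
#' A `discrete_dataset` is the discrete counterpart of a
#' [time_series_set()]: every entry is an integer state in `0..k-1`, with the
#' same state count `k` for every gene (variable uniformity, required by the
#' global search).
#'
#' @param series a matrix or list of integer matrices with entries in
#'   `0..k-1`.
#' @param k number of discrete states (`>= 2`).
#' @param gene_ids as in [time_series_set()].
#' @return an object of class `discrete_dataset` with fields `series`,
#'   `gene_ids`, `k`, `n`, `m`.
#' @export
discrete_dataset <- function(series, k, gene_ids = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_invalid("`k` must be an integer >= 2")
  if (is.matrix(series)) series <- list(series)
  tss <- time_series_set(series, gene_ids)
  series <- lapply(tss$series, function(s) {
    if (any(s != round(s))) stop_invalid("discrete series must be integer-valued")
    si <- s
    storage.mode(si) <- "integer"
    if (any(si < 0L | si >= k))
      stop_invalid("discrete states must lie in 0..k-1")
    si
  })
  structure(list(series = series, gene_ids = tss$gene_ids, k = k,
                 n = tss$n, m = tss$m),
            class = "discrete_dataset")
}

#' Reinterpret an already-discrete time series set as a discrete dataset
#'
#' Used for simulator output whose values are already states in `0..k-1`; no
#' quantile binning is applied.
#'
#' @param tss a [time_series_set()] with integer-valued entries.
#' @param k number of states.
#' @return a [discrete_dataset()].
#' @export
as_discrete_dataset <- function(tss, k) {
  stopifnot(inherits(tss, "time_series_set"))
  discrete_dataset(tss$series, k = k, gene_ids = tss$gene_ids)
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("<discrete_dataset> %d genes, %d series, k = %d states\n",
              x$n, x$m, x$k))
  invisible(x)
}

#' Quantile discretization into k equal-frequency states
#'
#' Per gene, values pooled across all series are split into `k`
#' equal-frequency bins at the empirical quantiles `j/k`; the 0-based bin
#' index (ascending value) becomes the state.  The same thresholds are
#' applied to every series of that gene, and a value exactly equal to a bin
#' edge is assigned to the lower bin.  Being rank-based, the result is
#' invariant to strictly monotone transforms of a gene's values.  Genes with
#' fewer than `k` distinct pooled values trigger a warning and may occupy
#' fewer than `k` states.
#'
#' @param tss a [time_series_set()].
#' @param k number of states (`>= 2`); 3 is the common choice for microarray
#'   time courses (low / baseline / high expression).
#' @return a [discrete_dataset()].
#' @examples
#' tss <- time_series_set(matrix(1:9, 1, 9))
#' quantile_discretize(tss, 3)$series[[1]]
#' @export
quantile_discretize <- function(tss, k) {
  stopifnot(inherits(tss, "time_series_set"))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_invalid("`k` must be an integer >= 2")
  n <- tss$n
  degenerate <- character(0)
  out <- lapply(tss$series, function(s) matrix(0L, nrow(s), ncol(s),
                                               dimnames = dimnames(s)))
  for (g in seq_len(n)) {
    pooled <- unlist(lapply(tss$series, function(s) s[g, ]), use.names = FALSE)
    if (length(pooled) < k)
      stop_invalid("gene ", tss$gene_ids[g], " has fewer than k observations")
    if (length(unique(pooled)) < k) degenerate <- c(degenerate, tss$gene_ids[g])
    edges <- stats::quantile(pooled, probs = seq_len(k - 1L) / k,
                             names = FALSE, type = 7)
    for (i in seq_along(tss$series)) {
      v <- tss$series[[i]][g, ]
      st <- rowSums(outer(v, edges, ">"))
      out[[i]][g, ] <- as.integer(st)
    }
  }
  if (length(degenerate) > 0L)
    warning("gene(s) with fewer than k distinct values; bins are unbalanced: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  discrete_dataset(out, k = k, gene_ids = tss$gene_ids)
}

#' Cubic-spline upsampling of a time series set
#'
#' Inserts `insert` interpolated points between each pair of consecutive
#' measurements, turning a series of length `Ni` into one of length
#' `Ni + (Ni - 1) * insert`.  Original samples are preserved exactly at their
#' positions; inserted values lie on a cubic interpolating spline through the
#' originals at evenly spaced abscissae (linear interpolation for series
#' shorter than 4 points).  Used to refine coarsely sampled time courses
#' before fitting a high-order model, e.g. 12 points with `insert = 2` give
#' 34 points at a third of the original sampling gap.
#'
#' @param tss a [time_series_set()].
#' @param insert non-negative integer: interpolated points per gap.
#' @return a [time_series_set()].
#' @export
spline_upsample <- function(tss, insert) {
  stopifnot(inherits(tss, "time_series_set"))
  insert <- as.integer(insert)
  if (is.na(insert) || insert < 0L) stop_invalid("`insert` must be >= 0")
  if (insert == 0L) return(tss)
  series <- lapply(tss$series, function(s) {
    ni <- ncol(s)
    xout <- seq(1, ni, by = 1 / (insert + 1L))
    out <- matrix(0, nrow(s), length(xout), dimnames = list(rownames(s), NULL))
    for (g in seq_len(nrow(s))) {
      y <- s[g, ]
      fit <- if (ni < 4L) {
        stats::approx(seq_len(ni), y, xout = xout)$y
      } else {
        stats::spline(seq_len(ni), y, xout = xout, method = "fmm")$y
      }
      # exact preservation of the measured values
      fit[seq(1, length(xout), by = insert + 1L)] <- y
      out[g, ] <- fit
    }
    out
  })
  time_series_set(series, gene_ids = tss$gene_ids)
}

#' Average replicate series point-wise
#'
#' When replicate time courses show the same dynamics (as for repeated
#' experiments on the same system), their arithmetic mean per gene and time
#' point is a common single-series summary used as learner input.
#'
#' @param tss a [time_series_set()] whose series all have equal length.
#' @return a single-series [time_series_set()].
#' @export
average_replicates <- function(tss) {
  stopifnot(inherits(tss, "time_series_set"))
  lens <- vapply(tss$series, ncol, 1L)
  if (length(unique(lens)) != 1L)
    stop_invalid("replicate averaging requires series of equal length")
  avg <- Reduce(`+`, tss$series) / tss$m
  time_series_set(avg, gene_ids = tss$gene_ids)
}

usable_series <- function(dataset, d, warn = TRUE) {
  lens <- vapply(dataset$series, ncol, 1L)
  keep <- lens > d
  if (any(!keep) && warn)
    warning(sum(!keep), " series with length <= d dropped from alignment",
            call. = FALSE)
  if (!any(keep)) stop_invalid("empty data: no series longer than d")
  which(keep)
}

#' Effective observations for a d-th order model
#'
#' Each series of length `Ni` contributes `Ni - d` aligned samples, so the
#' total is `Ne = sum(Ni) - m * d` over the usable series.  Series with
#' `Ni <= d` are dropped with a warning.
#'
#' @param dataset a [discrete_dataset()] (or [time_series_set()]).
#' @param d Markov order (`>= 1`): the maximum permitted regulation lag.
#' @return integer count `Ne`.
#' @examples
#' dd <- discrete_dataset(matrix(rep(0:1, 25), 1), k = 2)
#' effective_observations(dd, 1)  # 49
#' @export
effective_observations <- function(dataset, d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop_invalid("`d` must be an integer >= 1")
  use <- usable_series(dataset, d)
  lens <- vapply(dataset$series[use], ncol, 1L)
  as.integer(sum(lens - d))
}

#' Lag-aware sample alignment for one child gene
#'
#' Builds the table the time-delayed mutual information is estimated from:
#' within each series independently, for every time `t` in `d+1..Ni` one row
#' pairs the child value `x_child[t]` with each parent value
#' `x_parent[t - lag]`.  Rows from all series are concatenated; no row ever
#' spans a series boundary.  The row count equals
#' [effective_observations()] for the same `(dataset, d)`.
#'
#' @param dataset a [discrete_dataset()].
#' @param child gene index (1-based) or gene id.
#' @param parents a [lagged_parents()] set (possibly empty); every lag must
#'   satisfy `1 <= lag <= d`.
#' @param d Markov order.
#' @return a list of class `aligned_samples` with `child` (integer vector of
#'   length `Ne`), `parents` (`Ne x s` integer matrix), `ne`, and `d`.
#' @export
align_samples <- function(dataset, child, parents, d) {
  stopifnot(inherits(dataset, "discrete_dataset"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop_invalid("`d` must be an integer >= 1")
  child <- resolve_gene(dataset, child)
  parents <- as_lagged_parents(parents, dataset)
  if (nrow(parents) > 0L && (any(parents$lag < 1L) || any(parents$lag > d)))
    stop_invalid("parent lags must satisfy 1 <= lag <= d (inter-slice edges only)")
  use <- usable_series(dataset, d)
  ch <- integer(0)
  pa <- matrix(integer(0), nrow = 0L, ncol = nrow(parents))
  for (i in use) {
    s <- dataset$series[[i]]
    ni <- ncol(s)
    t <- (d + 1L):ni
    ch <- c(ch, s[child, t])
    if (nrow(parents) > 0L) {
      block <- vapply(seq_len(nrow(parents)), function(j) {
        s[parents$gene[j], t - parents$lag[j]]
      }, integer(length(t)))
      if (is.null(dim(block))) block <- matrix(block, nrow = length(t))
      pa <- rbind(pa, block)
    } else {
      pa <- rbind(pa, matrix(integer(0), length(t), 0L))
    }
  }
  if (length(ch) < 1L) stop_invalid("empty alignment: Ne < 1")
  structure(list(child = as.integer(ch), parents = pa,
                 ne = length(ch), d = d),
            class = "aligned_samples")
}

resolve_gene <- function(dataset, gene) {
  if (is.character(gene)) {
    idx <- match(gene, dataset$gene_ids)
    if (is.na(idx)) stop_invalid("unknown gene id: ", gene)
    return(idx)
  }
  gene <- as.integer(gene)
  if (is.na(gene) || gene < 1L || gene > dataset$n)
    stop_invalid("gene index out of range")
  gene
}
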