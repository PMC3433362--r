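# Readers and writers for the TSV dialects: expression matrices (first
# column gene id, header row of time labels), truth networks
# (regulator / target / lag), and learned-network exports (TSV, SIF,
# GraphML).

#' Read time-course expression data from TSV
#'
#' Each file holds a genes-in-rows matrix: first column gene id, header row
#' of time labels.  Multiple series are supplied either as multiple files or
#' as one file whose columns are split by `series_lengths`.
#'
#' @param files character vector of paths.
#' @param series_lengths optional integer vector splitting the columns of a
#'   single file into consecutive series.
#' @param transpose set `TRUE` for files with time in rows and genes in
#'   columns.
#' @return a [time_series_set()].
#' @export
read_expression_tsv <- function(files, series_lengths = NULL,
                                transpose = FALSE) {
  mats <- lapply(files, function(f) {
    df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "double"
    if (transpose) m <- t(m)
    colnames(m) <- NULL
    m
  })
  if (!is.null(series_lengths)) {
    if (length(mats) != 1L)
      stop_invalid("`series_lengths` applies to a single input file")
    m <- mats[[1L]]
    series_lengths <- as.integer(series_lengths)
    if (sum(series_lengths) != ncol(m))
      stop_invalid("series lengths must sum to the column count (",
                   ncol(m), ")")
    ends <- cumsum(series_lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    mats <- lapply(seq_along(ends), function(i) m[, starts[i]:ends[i],
                                                  drop = FALSE])
  }
  time_series_set(mats)
}

#' Write a time series set to TSV
#'
#' Series are written side by side (concatenated columns); re-read with
#' `series_lengths = sapply(tss$series, ncol)`.
#'
#' @param tss a [time_series_set()] or [discrete_dataset()].
#' @param file output path.
#' @export
write_expression_tsv <- function(tss, file) {
  m <- do.call(cbind, tss$series)
  df <- data.frame(gene = tss$gene_ids, m, check.names = FALSE)
  colnames(df) <- c("gene", paste0("t", seq_len(ncol(m))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a discrete expression matrix from TSV
#'
#' Same dialect as [read_expression_tsv()] with integer entries in
#' `0..k-1`.
#'
#' @inheritParams read_expression_tsv
#' @param k number of states.
#' @return a [discrete_dataset()].
#' @export
read_discrete_tsv <- function(files, k, series_lengths = NULL,
                              transpose = FALSE) {
  as_discrete_dataset(read_expression_tsv(files, series_lengths, transpose), k)
}

#' Read / write ground-truth lagged edge lists
#'
#' TSV with columns `regulator`, `target`, `lag`.
#'
#' @param file path.
#' @param nodes optional full node universe (defaults to the genes present
#'   in the edge list).
#' @return a [truth_network()].
#' @export
read_truth_network <- function(file, nodes = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$regulator, df$target)))
  truth_network(nodes, df)
}

#' @rdname read_truth_network
#' @param network a [truth_network()] or [dbn_network()].
#' @export
write_truth_network <- function(network, file) {
  e <- as_edge_list(network)[, c("regulator", "target", "lag")]
  utils::write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a learned network
#'
#' Formats: `"tsv"` — edge list `regulator, target, lag, delta_mi`
#' (`delta_mi` is the mutual-information gain when the parent is added
#' last, usable for ranking); `"sif"` — Cytoscape SIF lines
#' `regulator lag<l> target`; `"graphml"` — via the igraph package.
#'
#' @param network a [dbn_network()].
#' @param file output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @export
write_network <- function(network, file, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- as_edge_list(network)
  if (format == "tsv") {
    utils::write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s lag%d %s", e$regulator, e$lag, e$target)
    writeLines(lines, file)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop_invalid("GraphML export requires the igraph package")
    nodes <- if (inherits(network, "dbn_network")) network$gene_ids
             else attr(network, "nodes")
    g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                       vertices = data.frame(name = nodes))
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}
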