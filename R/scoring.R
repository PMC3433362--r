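# MIT scoring machinery: shifted entropies, time-delayed joint mutual
# information, chi-square penalties, and the per-node decomposition
# s = v + u minimized by the global search.
#
# All information quantities use the natural logarithm: the chi-square
# calibration of 2N*I (the G-statistic) holds in nats.  Probabilities are
# plug-in (maximum-likelihood) estimates from raw counts, which keeps
# I(X, empty set) = 0 exact and the asymptotics standard.

entropy_from_codes <- function(codes) {
  n <- length(codes)
  cnt <- tabulate(match(codes, unique(codes)))
  log(n) - sum(cnt * log(cnt)) / n
}

joint_codes <- function(mat, k) {
  if (ncol(mat) == 0L) return(rep.int(0L, nrow(mat)))
  as.vector(mat %*% k^(seq_len(ncol(mat)) - 1L))
}

#' Shifted entropy of a gene
#'
#' Plug-in entropy (in nats) of the child column of the d-shifted alignment,
#' i.e. of the observations `x[d+1], ..., x[Ni]` concatenated over series.
#' This is the entropy that upper-bounds the time-delayed mutual information
#' of the gene with any parent set, and drives the tight stopping rule of
#' the search.
#'
#' @param dataset a [discrete_dataset()].
#' @param gene gene index or id.
#' @param d Markov order.
#' @return entropy in nats.
#' @export
shifted_entropy <- function(dataset, gene, d) {
  al <- align_samples(dataset, gene, lagged_parents(), d)
  entropy_from_codes(al$child)
}

#' Time-delayed mutual information
#'
#' Mutual information (nats, plug-in) between a child gene and the joint
#' configuration of its lagged parents, computed on the lag-aware alignment
#' of [align_samples()].  The empty parent set returns exactly 0.
#'
#' @inheritParams align_samples
#' @return mutual information in nats.
#' @export
time_delayed_mi <- function(dataset, child, parents, d) {
  parents <- as_lagged_parents(parents, dataset)
  if (nrow(parents) == 0L) return(0)
  al <- align_samples(dataset, child, parents, d)
  hy <- entropy_from_codes(al$child)
  pj <- joint_codes(al$parents, dataset$k)
  hj <- entropy_from_codes(pj)
  hjy <- entropy_from_codes(pj * dataset$k + al$child)
  hy + hj - hjy
}

#' Chi-square penalty degrees of freedom for a parent set
#'
#' The MIT penalty charges each added parent a chi-square quantile whose
#' degrees of freedom depend on the state counts.  Parents are sorted by
#' state count descending (the permutation sigma); the j-th sorted parent
#' with `r_j` states contributes
#' `l_j = (r_child - 1) (r_j - 1) prod_{m<j} r_m` (and simply
#' `(r_child - 1)(r_1 - 1)` for `j = 1`).  Under variable uniformity
#' (all state counts equal `k`) this reduces to `(k-1)^2 * k^(j-1)`.
#'
#' @param r_child number of states of the child (`>= 2`).
#' @param r_parents integer vector of parent state counts (possibly empty).
#' @return integer vector of degrees of freedom, one per parent, in sigma
#'   order.
#' @examples
#' penalty_dof(3, c(3, 3))   # (4, 12)
#' penalty_dof(3, c(2, 4))   # (6, 8)
#' @export
penalty_dof <- function(r_child, r_parents) {
  r_child <- as.integer(r_child)
  r_parents <- as.integer(r_parents)
  if (r_child < 2L || (length(r_parents) > 0L && any(r_parents < 2L)))
    stop_invalid("state counts must be >= 2")
  if (length(r_parents) == 0L) return(integer(0))
  r <- sort(r_parents, decreasing = TRUE)
  s <- length(r)
  l <- numeric(s)
  for (j in seq_len(s)) {
    prodprev <- if (j == 1L) 1 else prod(r[seq_len(j - 1L)])
    l[j] <- (r_child - 1) * (r[j] - 1) * prodprev
  }
  l
}

dof_guard <- 1e7

#' Precomputed chi-square penalty table
#'
#' Entry `j` of `chi_values` is the alpha-quantile of the chi-square
#' distribution with `(k-1)^2 * k^(j-1)` degrees of freedom — the penalty for
#' the j-th parent added under variable uniformity; `cumulative[p]` is
#' `U(p)`, the total penalty of any parent set of cardinality `p`.  Degrees
#' of freedom beyond 1e7 raise an error rather than risking silent numeric
#' failure.
#'
#' @param alpha significance level in (0, 1); high values (0.999-0.9999)
#'   penalize complexity more strongly.
#' @param k uniform number of discrete states.
#' @param max_p largest parent-set cardinality tabulated.
#' @return an object of class `penalty_table` with fields `alpha`, `k`,
#'   `chi_values`, `cumulative`.
#' @examples
#' pt <- build_penalty_table(0.999, 3, 2)
#' pt$cumulative[2]  # ~51.376
#' @export
build_penalty_table <- function(alpha, k, max_p = 20L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must lie strictly between 0 and 1")
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_invalid("`k` must be an integer >= 2")
  max_p <- as.integer(max_p)
  dof <- (k - 1)^2 * k^(seq_len(max_p) - 1)
  if (any(dof > dof_guard))
    stop_invalid("penalty degrees of freedom exceed guard (1e7); reduce max_p")
  chi <- stats::qchisq(alpha, df = dof)
  structure(list(alpha = alpha, k = k, chi_values = chi,
                 cumulative = cumsum(chi)),
            class = "penalty_table")
}

# U(p) with on-demand extension of the table.
penalty_sum <- function(pt, p) {
  if (p == 0L) return(0)
  if (p > length(pt$cumulative))
    pt <- build_penalty_table(pt$alpha, pt$k, p)
  pt$cumulative[p]
}

resolve_alpha <- function(alpha, ne) {
  if (identical(alpha, "auto") || is.null(alpha)) {
    if (ne < 100) 0.999 else 0.9999
  } else {
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
      stop_invalid("`alpha` must be 'auto' or a number in (0, 1)")
    alpha
  }
}

#' Score a parent set for one child gene
#'
#' Decomposes the per-node MIT objective into an error term
#' `v = 2 Ne (B - Is(child, parents))` — where the bound `B` is the shifted
#' entropy of the child (`bound = "entropy"`, tighter, the default) or
#' `log(k)` (`bound = "logk"`) — and a complexity term
#' `u = U(|parents|)`, the cumulative chi-square penalty.  The total
#' `s = v + u` is what the global search minimizes; both `v` and `u` are
#' non-negative, and `u` depends only on the cardinality of the parent set
#' under variable uniformity.
#'
#' @inheritParams align_samples
#' @param alpha significance level or `"auto"` (0.999 if `Ne < 100`, else
#'   0.9999).
#' @param bound `"entropy"` or `"logk"`.
#' @return a list of class `score_parts` with `v`, `u`, `s`, `mi`, `ne`,
#'   `alpha`, `bound`.
#' @export
parent_set_score <- function(dataset, child, parents, d, alpha = "auto",
                             bound = c("entropy", "logk")) {
  bound <- match.arg(bound)
  parents <- as_lagged_parents(parents, dataset)
  ne <- effective_observations(dataset, d)
  alpha <- resolve_alpha(alpha, ne)
  mi <- time_delayed_mi(dataset, child, parents, d)
  b <- if (bound == "entropy") shifted_entropy(dataset, child, d) else log(dataset$k)
  v <- max(0, 2 * ne * (b - mi))
  pt <- build_penalty_table(alpha, dataset$k, max(1L, nrow(parents)))
  u <- penalty_sum(pt, nrow(parents))
  structure(list(v = v, u = u, s = v + u, mi = mi, ne = ne,
                 alpha = alpha, bound = bound),
            class = "score_parts")
}

#' @export
print.score_parts <- function(x, ...) {
  cat(sprintf("<score_parts> s = %.4f (v = %.4f, u = %.4f), Is = %.4f nats, Ne = %d\n",
              x$s, x$v, x$u, x$mi, x$ne))
  invisible(x)
}

#' Score a whole transition network
#'
#' Returns both orientations of the MIT objective: the higher-is-better
#' network score `S'' = sum over genes with non-empty parent sets of
#' `2 Ne Is(child, parents) - U(|parents|)`, and the lower-is-better sum of
#' per-node `s` parts used by the search.  The two orderings are equivalent
#' (they differ by the constant `sum_i 2 Ne B_i`).
#'
#' When `assume_uniform = FALSE` the general penalty of [penalty_dof()] is
#' applied using each variable's observed number of states; this is supported
#' for scoring a user-supplied network only — the global search requires
#' variable uniformity.
#'
#' @param dataset a [discrete_dataset()].
#' @param network a [dbn_network()] with lags `<= d`.
#' @param d Markov order.
#' @inheritParams parent_set_score
#' @param assume_uniform if `FALSE`, use per-variable observed state counts
#'   in the penalty (general scoring).
#' @return list with `s_mit_max` (S''), `s_mit_min` (sum of per-node s),
#'   and a per-node data frame `nodes`.
#' @export
network_score <- function(dataset, network, d, alpha = "auto",
                          bound = c("entropy", "logk"),
                          assume_uniform = TRUE) {
  stopifnot(inherits(dataset, "discrete_dataset"),
            inherits(network, "dbn_network"))
  bound <- match.arg(bound)
  d <- as.integer(d)
  for (ps in network$parent_sets)
    if (nrow(ps) > 0L && any(ps$lag > d))
      stop_invalid("invalid network: lag exceeds order d")
  ne <- effective_observations(dataset, d)
  alpha <- resolve_alpha(alpha, ne)
  k <- dataset$k
  obs_states <- if (!assume_uniform) {
    vapply(seq_len(dataset$n), function(g) {
      vals <- unlist(lapply(dataset$series, function(s) s[g, ]))
      max(2L, length(unique(vals)))
    }, 1L)
  } else NULL
  pt <- build_penalty_table(alpha, k, 1L)
  rows <- lapply(seq_len(dataset$n), function(i) {
    ps <- network$parent_sets[[i]]
    mi <- time_delayed_mi(dataset, i, ps, d)
    u <- if (assume_uniform) {
      penalty_sum(pt, nrow(ps))
    } else if (nrow(ps) == 0L) 0 else {
      dof <- penalty_dof(obs_states[i], obs_states[ps$gene])
      if (any(dof > dof_guard)) stop_invalid("penalty dof guard exceeded")
      sum(stats::qchisq(alpha, df = dof))
    }
    b <- if (bound == "entropy") shifted_entropy(dataset, i, d) else log(k)
    v <- max(0, 2 * ne * (b - mi))
    data.frame(gene = dataset$gene_ids[i], n_parents = nrow(ps),
               mi = mi, v = v, u = u, s = v + u,
               contrib = if (nrow(ps) > 0L) 2 * ne * mi - u else 0)
  })
  nodes <- do.call(rbind, rows)
  list(s_mit_max = sum(nodes$contrib), s_mit_min = sum(nodes$s),
       ne = ne, alpha = alpha, bound = bound, nodes = nodes)
}

#' Write a per-node score report
#'
#' TSV audit log of (gene, parent count, Is, v, u, s) for a scored network.
#'
#' @param score result of [network_score()].
#' @param file output path.
#' @export
write_score_report <- function(score, file) {
  df <- score$nodes[, c("gene", "n_parents", "mi", "v", "u", "s")]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
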