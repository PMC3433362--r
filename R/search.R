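# Globally optimal parent-set search.
#
# For every child gene the candidate regulators are the lagged variables
# X_g[t - lag]; the search walks parent-set cardinalities p = 1, 2, ...
# exhaustively (lexicographic enumeration, compiled), keeping the incumbent
# with the minimal s = v + u.  Before enumerating a cardinality it tests the
# stopping rule u(p) >= s(incumbent): since v >= 0 and u depends only on
# cardinality, no set of size >= p can beat the incumbent, which makes the
# returned set globally optimal while bounding the enumerated cardinality by
# p* = O(log_k Ne).

# Aligned design shared by all children of one dataset: `child` holds the
# d-shifted target columns, `lagged` the candidate columns, ordered by
# (gene, lag) with lag minor -- column (g - 1) * d + lag.
alignment_frame <- function(dataset, d) {
  use <- usable_series(dataset, d, warn = FALSE)
  n <- dataset$n
  childs <- vector("list", length(use))
  lags <- vector("list", length(use))
  for (ii in seq_along(use)) {
    s <- dataset$series[[use[ii]]]
    t <- (d + 1L):ncol(s)
    childs[[ii]] <- t(s[, t, drop = FALSE])
    block <- matrix(0L, length(t), n * d)
    for (g in seq_len(n)) {
      for (dl in seq_len(d)) block[, (g - 1L) * d + dl] <- s[g, t - dl]
    }
    lags[[ii]] <- block
  }
  child <- do.call(rbind, childs)
  lagged <- do.call(rbind, lags)
  storage.mode(child) <- "integer"
  storage.mode(lagged) <- "integer"
  list(child = child, lagged = lagged, ne = nrow(child), d = d, n = n)
}

candidate_frame <- function(frame, candidates) {
  idx <- (candidates$gene - 1L) * frame$d + candidates$lag
  frame$lagged[, idx, drop = FALSE]
}

# Level-wise exhaustive search with the chi-square stopping rule.
mit_level_search <- function(childcol, cand, candidates, k, ne, alpha,
                             bound, hs) {
  b <- if (bound == "entropy") hs else log(k)
  pt <- build_penalty_table(alpha, k, 1L)
  s_best <- 2 * ne * b
  best <- integer(0)
  C <- ncol(cand)
  trace <- list()
  stopped_at <- NA_integer_
  for (p in seq_len(C)) {
    pt_p <- if (p > length(pt$cumulative)) build_penalty_table(alpha, k, p) else pt
    pt <- pt_p
    u_p <- pt$cumulative[p]
    if (u_p >= s_best) {
      stopped_at <- p
      trace[[p]] <- data.frame(p = p, u = u_p, incumbent_before = s_best,
                               n_subsets = 0, enumerated = FALSE,
                               best_s = NA_real_)
      break
    }
    res <- .mit_best_subset(cand, childcol, k, p)
    v <- max(0, 2 * ne * (b - res$mi))
    s <- v + u_p
    trace[[p]] <- data.frame(p = p, u = u_p, incumbent_before = s_best,
                             n_subsets = res$n_evaluated, enumerated = TRUE,
                             best_s = s)
    if (s < s_best) {
      s_best <- s
      best <- res$subset
    }
  }
  trace <- do.call(rbind, trace)
  if (is.null(trace))
    trace <- data.frame(p = integer(0), u = numeric(0),
                        incumbent_before = numeric(0), n_subsets = numeric(0),
                        enumerated = logical(0), best_s = numeric(0))
  parents <- lagged_parents(candidates$gene[best], candidates$lag[best])
  mi_best <- if (length(best) > 0L) {
    # recover Is of the incumbent from s = 2 Ne (b - Is) + u
    (2 * ne * b - (s_best - pt$cumulative[length(best)])) / (2 * ne)
  } else 0
  pb <- pstar_bound(ne, k, alpha, hs = if (bound == "entropy") hs else NULL)
  trace <- structure(trace, pstar = pb$pstar, pstar_closed_form = pb$closed_form,
                     n_candidates = C, stopped_at = stopped_at)
  u_best <- penalty_sum(pt, nrow(parents))
  score <- structure(list(v = s_best - u_best, u = u_best, s = s_best,
                          mi = mi_best, ne = ne, alpha = alpha, bound = bound),
                     class = "score_parts")
  list(parents = parents, score = score, trace = trace)
}

finish_fit <- function(fit, dataset, child, d) {
  structure(list(child = child, child_id = dataset$gene_ids[child],
                 parents = fit$parents, score = fit$score, trace = fit$trace),
            class = "mit_fit")
}

#' @export
print.mit_fit <- function(x, ...) {
  cat(sprintf("<mit_fit> child %s: %d parent(s), s = %.4f\n",
              x$child_id, nrow(x$parents), x$score$s))
  invisible(x)
}

check_search_input <- function(dataset, d) {
  stopifnot(inherits(dataset, "discrete_dataset"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop_invalid("`d` must be an integer >= 1")
  # Assumption of variable uniformity is structural in discrete_dataset (one
  # k for all genes); refuse datasets that claim more states than observed
  # nowhere -- the constructor already enforces range.
  d
}

#' Globally optimal lagged parent set (GlobalMIT+)
#'
#' Exhaustive-by-cardinality search over all subsets of the `n * d` lagged
#' candidate variables (all genes at all lags `1..d`, including the child
#' itself unless `allow_self = FALSE`).  The chi-square stopping rule makes
#' the result provably the global minimizer of the per-node score `s`;
#' replacement requires strict improvement and enumeration is lexicographic
#' over candidates ordered by (gene, lag), so ties resolve to the smallest
#' cardinality and then the lexicographically first set.
#'
#' @param dataset a [discrete_dataset()] (uniform state count `k`).
#' @param child gene index or id.
#' @param d Markov order.
#' @param alpha significance level or `"auto"` (0.999 if `Ne < 100`, else
#'   0.9999).
#' @param bound stopping bound: `"entropy"` (shifted child entropy, tighter,
#'   default) or `"logk"`.
#' @param allow_self permit self-regulation `X[t - lag] -> X[t]`.
#' @param frame internal precomputed alignment (used by [learn_network()]).
#' @return an object of class `mit_fit`: `parents` ([lagged_parents()]),
#'   `score` (`score_parts`), and `trace` (per-cardinality search log with
#'   attributes `pstar`, `pstar_closed_form`, `n_candidates`).
#' @export
learn_parents_plus <- function(dataset, child, d, alpha = "auto",
                               bound = c("entropy", "logk"),
                               allow_self = TRUE, frame = NULL) {
  bound <- match.arg(bound)
  d <- check_search_input(dataset, d)
  child <- resolve_gene(dataset, child)
  if (is.null(frame)) frame <- alignment_frame(dataset, d)
  ne <- frame$ne
  alpha <- resolve_alpha(alpha, ne)
  candidates <- data.frame(gene = rep(seq_len(dataset$n), each = d),
                           lag = rep(seq_len(d), dataset$n))
  if (!allow_self) candidates <- candidates[candidates$gene != child, ]
  cand <- candidate_frame(frame, candidates)
  childcol <- frame$child[, child]
  hs <- entropy_from_codes(childcol)
  fit <- mit_level_search(childcol, cand, candidates, dataset$k, ne, alpha,
                          bound, hs)
  finish_fit(fit, dataset, child, d)
}

#' Optimal lag per candidate regulator (Assumption of non-redundant,
#' optimal-lag interactions)
#'
#' For each gene, the lag in `1..d` maximizing the pairwise time-delayed
#' mutual information with the child; ties break toward the smallest lag.
#' This is the per-child lag restriction that gives GlobalMIT* the candidate
#' set size of a first-order search.
#'
#' @inheritParams learn_parents_plus
#' @return named integer vector of length `n` (best lag per gene).
#' @export
optimal_lag_table <- function(dataset, child, d, frame = NULL) {
  d <- check_search_input(dataset, d)
  child <- resolve_gene(dataset, child)
  if (is.null(frame)) frame <- alignment_frame(dataset, d)
  childcol <- frame$child[, child]
  mi <- .mit_pairwise_mi(frame$lagged, childcol, dataset$k)
  mim <- matrix(mi, nrow = d)  # rows = lags, cols = genes
  best <- apply(mim, 2L, which.max)  # first max: smallest lag on ties
  stats::setNames(as.integer(best), dataset$gene_ids)
}

#' Globally optimal parent set over lag-restricted candidates (GlobalMIT*)
#'
#' Runs the same level-wise search as [learn_parents_plus()], but over the
#' `n` candidates fixed by [optimal_lag_table()] (one lag per regulator
#' gene).  For `d = 1` the two searches coincide; for `d > 1` this trades a
#' little coverage for a search-space size independent of `d`.
#'
#' @inheritParams learn_parents_plus
#' @return an object of class `mit_fit` (see [learn_parents_plus()]).
#' @export
learn_parents_star <- function(dataset, child, d, alpha = "auto",
                               bound = c("entropy", "logk"),
                               allow_self = TRUE, frame = NULL) {
  bound <- match.arg(bound)
  d <- check_search_input(dataset, d)
  child <- resolve_gene(dataset, child)
  if (is.null(frame)) frame <- alignment_frame(dataset, d)
  ne <- frame$ne
  alpha <- resolve_alpha(alpha, ne)
  lags <- optimal_lag_table(dataset, child, d, frame = frame)
  candidates <- data.frame(gene = seq_len(dataset$n), lag = as.integer(lags))
  if (!allow_self) candidates <- candidates[candidates$gene != child, ]
  cand <- candidate_frame(frame, candidates)
  childcol <- frame$child[, child]
  hs <- entropy_from_codes(childcol)
  fit <- mit_level_search(childcol, cand, candidates, dataset$k, ne, alpha,
                          bound, hs)
  finish_fit(fit, dataset, child, d)
}

#' Learn the whole transition network
#'
#' Applies the per-node learner to every gene.  Because only inter-slice
#' edges are modeled, nodes are independent: the output is bit-identical
#' regardless of `threads` or node execution order.
#'
#' @inheritParams learn_parents_plus
#' @param variant `"plus"` (search all `n * d` lagged candidates) or
#'   `"star"` (one optimal lag per regulator).
#' @param threads worker processes for per-node parallelism (results are
#'   merged by node index; determinism is unaffected).
#' @param verbose print a per-node search summary.
#' @return a [dbn_network()]; parent sets carry a `delta_mi` column (the Is
#'   gain when that parent is added last).  Attributes `fits` (per-node
#'   `mit_fit` objects) and `ne`, `alpha` record the run.
#' @export
learn_network <- function(dataset, d, alpha = "auto",
                          variant = c("plus", "star"),
                          bound = c("entropy", "logk"),
                          allow_self = TRUE, threads = 1L, verbose = FALSE) {
  variant <- match.arg(variant)
  bound <- match.arg(bound)
  d <- check_search_input(dataset, d)
  frame <- alignment_frame(dataset, d)
  alpha_res <- resolve_alpha(alpha, frame$ne)
  learner <- if (variant == "plus") learn_parents_plus else learn_parents_star
  one <- function(i) {
    fit <- learner(dataset, i, d, alpha = alpha_res, bound = bound,
                   allow_self = allow_self, frame = frame)
    if (verbose) {
      tr <- fit$trace
      cat(sprintf("node=%s p_max=%s subsets=%g best_s=%.4f\n",
                  dataset$gene_ids[i],
                  if (is.null(tr)) 0 else max(tr$p[tr$enumerated]),
                  if (is.null(tr)) 0 else sum(tr$n_subsets), fit$score$s))
    }
    fit
  }
  fits <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(dataset$n), one, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(dataset$n), one)
  }
  parent_sets <- lapply(seq_len(dataset$n), function(i) {
    ps <- fits[[i]]$parents
    if (nrow(ps) > 0L) {
      ps$delta_mi <- vapply(seq_len(nrow(ps)), function(j) {
        fits[[i]]$score$mi -
          time_delayed_mi(dataset, i, ps[-j, c("gene", "lag")], d)
      }, 0)
    }
    ps
  })
  net <- dbn_network(parent_sets, d, dataset$gene_ids)
  attr(net, "fits") <- fits
  attr(net, "ne") <- frame$ne
  attr(net, "alpha") <- alpha_res
  attr(net, "variant") <- variant
  net
}

#' Cardinality bound p* of the level-wise search
#'
#' The smallest `p` whose cumulative penalty `U(p)` reaches the score of the
#' empty parent set — no cardinality `>= p*` is ever enumerated.  The
#' threshold is `2 ne hs` when the shifted entropy `hs` is supplied (entropy
#' bound), else `2 ne log(k)`.  Also returns the closed-form over-estimate
#' `ceiling(log_k(2 ne log k / (k - 1)) + 1)` obtained by replacing each
#' chi-square quantile with its mean.
#'
#' @param ne effective observations.
#' @param k uniform state count.
#' @param alpha significance level.
#' @param hs optional shifted entropy of the child (nats).
#' @return list with `pstar` (numeric bound), `closed_form` (over-estimate)
#'   and `threshold`.
#' @examples
#' pstar_bound(20, 3, 0.999)$pstar        # 2
#' pstar_bound(100, 3, 0.999)$closed_form # 6
#' @export
pstar_bound <- function(ne, k, alpha, hs = NULL) {
  if (!is.numeric(ne) || ne < 1) stop_invalid("`ne` must be >= 1")
  k <- as.integer(k)
  threshold <- 2 * ne * (if (is.null(hs)) log(k) else hs)
  p <- 0L
  u <- 0
  pt <- build_penalty_table(alpha, k, 1L)
  repeat {
    p <- p + 1L
    u <- penalty_sum(pt, p)
    if (u >= threshold) break
  }
  closed <- as.integer(ceiling(log(2 * ne * log(k) / (k - 1), base = k) + 1))
  list(pstar = p, closed_form = closed, threshold = threshold)
}

#' Brute-force parent-set oracle
#'
#' Enumerates every subset of the lagged candidates up to `max_card`
#' (lexicographic order, strict-improvement replacement — the same
#' deterministic tie policy as the search) and scores each with the plain R
#' scoring path.  Intended as an independent correctness check for
#' [learn_parents_plus()]; refuses instances with more than `1e6` subsets.
#'
#' @inheritParams learn_parents_plus
#' @param max_card largest cardinality enumerated.
#' @return list with `parents`, `score` (`s`, `v`, `u`, `mi`), and
#'   `n_subsets`.
#' @export
exhaustive_oracle <- function(dataset, child, d, alpha = "auto", max_card,
                              bound = c("entropy", "logk"),
                              allow_self = TRUE) {
  bound <- match.arg(bound)
  d <- check_search_input(dataset, d)
  child <- resolve_gene(dataset, child)
  ne <- effective_observations(dataset, d)
  alpha <- resolve_alpha(alpha, ne)
  candidates <- data.frame(gene = rep(seq_len(dataset$n), each = d),
                           lag = rep(seq_len(d), dataset$n))
  if (!allow_self) candidates <- candidates[candidates$gene != child, ]
  C <- nrow(candidates)
  max_card <- min(as.integer(max_card), C)
  total <- sum(choose(C, seq_len(max_card)))
  if (total > 1e6)
    stop_invalid("guard exceeded: ", format(total, big.mark = ","),
                 " subsets requested (limit 1e6)")
  k <- dataset$k
  b <- if (bound == "entropy") shifted_entropy(dataset, child, d) else log(k)
  pt <- build_penalty_table(alpha, k, max(1L, max_card))
  best_parents <- lagged_parents()
  best <- list(s = 2 * ne * b, v = 2 * ne * b, u = 0, mi = 0)
  n_subsets <- 0
  if (max_card >= 1L) {
    for (p in seq_len(max_card)) {
      u_p <- penalty_sum(pt, p)
      sets <- utils::combn(C, p)
      for (j in seq_len(ncol(sets))) {
        idx <- sets[, j]
        ps <- lagged_parents(candidates$gene[idx], candidates$lag[idx])
        mi <- time_delayed_mi(dataset, child, ps, d)
        s <- max(0, 2 * ne * (b - mi)) + u_p
        n_subsets <- n_subsets + 1
        if (s < best$s) {
          best <- list(s = s, v = s - u_p, u = u_p, mi = mi)
          best_parents <- ps
        }
      }
    }
  }
  list(parents = best_parents,
       score = structure(c(best, list(ne = ne, alpha = alpha, bound = bound)),
                         class = "score_parts"),
       n_subsets = n_subsets)
}
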