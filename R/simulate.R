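# Synthetic benchmark networks and seeded simulators.
#
# The flagship fixture mirrors the published design of a glucose-homeostasis
# benchmark: 35 genes organized in 4 levels, 52 interactions partitioned by
# regulation order into 13 first-, 23 second- and 16 third-order edges, data
# generated from a *static* Bayesian network and turned into a lagged system
# by shifting the profiles of level-l nodes forward by l - 1 time units.
# The exact published wiring is not legible from the source figure, so the
# packaged topology is a deterministic surrogate preserving the node count,
# level structure, per-order edge counts and multi-regulator in-degrees
# (flagged `surrogate = TRUE`).

#' Simulation specification
#'
#' @param q conditional-probability-table strength: the probability that a
#'   child obeys its deterministic parent rule; with probability `1 - q` it
#'   takes a uniform random state.  Must satisfy `0.5 < q <= 1`; the default
#'   0.9 represents interaction strengths consistent with biological
#'   variation.
#' @param m number of independent time series.
#' @param n_obs time points per series (before shift truncation for the
#'   static-then-shift generator).
#' @param k number of discrete states (2 for the glucose-style benchmark).
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(q = 0.9, m = 10L, n_obs = 125L, k = 2L, seed = 1L) {
  if (!is.numeric(q) || q <= 0.5 || q > 1)
    stop_invalid("`q` must satisfy 0.5 < q <= 1")
  m <- as.integer(m); n_obs <- as.integer(n_obs); k <- as.integer(k)
  if (m < 1L || n_obs < 2L || k < 2L) stop_invalid("invalid simulation sizes")
  structure(list(q = q, m = m, n_obs = n_obs, k = k, seed = as.integer(seed)),
            class = "sim_spec")
}

# Level sizes of the packaged 35-node cascade.
glucose_level_sizes <- c(6L, 8L, 10L, 11L)

#' The 35-gene glucose-homeostasis benchmark network
#'
#' A 4-level cascade of 35 genes and 52 lagged interactions: 13 first-order
#' (adjacent levels), 23 second-order and 16 third-order edges, with the top
#' level playing the master transcription factors.  Topology is a documented
#' deterministic surrogate (see package vignette); counts, level structure
#' and multi-regulator in-degrees match the published design.
#'
#' @return a [truth_network()] with a node -> level map and
#'   `surrogate = TRUE`.
#' @examples
#' net <- glucose_network()
#' table(net$lag)  # 13, 23, 16
#' @export
glucose_network <- function() {
  sizes <- glucose_level_sizes
  levels <- rep(seq_along(sizes), sizes)
  nodes <- sprintf("G%02d", seq_len(sum(sizes)))
  names(levels) <- nodes
  lv <- split(nodes, levels)
  rr <- function(pool, n) pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
  edges <- rbind(
    # order 1 (13): every level-2 node gets a master regulator (8), three
    # level-2 nodes get a second master (3), two level-3 nodes get a
    # level-2 regulator (2)
    data.frame(regulator = rr(lv[[1]], 8L), target = lv[[2]], lag = 1L),
    data.frame(regulator = rr(lv[[1]][4:6], 3L), target = lv[[2]][1:3], lag = 1L),
    data.frame(regulator = lv[[2]][1:2], target = lv[[3]][1:2], lag = 1L),
    # order 2 (23): every level-3 node regulated from level 1 (10), every
    # level-4 node regulated from level 2 (11), plus two extra level-2 ->
    # level-4 co-regulators
    data.frame(regulator = rr(lv[[1]], 10L), target = lv[[3]], lag = 2L),
    data.frame(regulator = rr(lv[[2]], 11L), target = lv[[4]], lag = 2L),
    data.frame(regulator = lv[[2]][3:4], target = lv[[4]][1:2], lag = 2L),
    # order 3 (16): master -> level-4 co-regulation, round-robin
    data.frame(regulator = rr(lv[[1]], 16L),
               target = rr(lv[[4]], 16L), lag = 3L))
  truth_network(nodes, edges, levels = levels, surrogate = TRUE)
}

#' Random leveled cascade network
#'
#' Seeded generalization of the glucose design: `n` nodes split evenly into
#' `levels` levels; for order `o` exactly `edges_per_order[o]` edges are
#' drawn uniformly among the node pairs whose level gap is `o`.
#'
#' @param n number of nodes.
#' @param levels number of levels.
#' @param edges_per_order integer vector: edge count for order 1, 2, ...
#'   (length at most `levels - 1`).
#' @param seed RNG seed.
#' @return a [truth_network()].
#' @export
random_cascade_network <- function(n, levels, edges_per_order, seed = 1L) {
  n <- as.integer(n); levels <- as.integer(levels)
  edges_per_order <- as.integer(edges_per_order)
  if (length(edges_per_order) > levels - 1L)
    stop_invalid("more orders requested than level gaps available")
  sizes <- rep(n %/% levels, levels)
  extra <- n %% levels
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lvl <- rep(seq_len(levels), sizes)
  nodes <- sprintf("g%02d", seq_len(n))
  names(lvl) <- nodes
  with_seed(seed, {
    rows <- lapply(seq_along(edges_per_order), function(o) {
      cnt <- edges_per_order[o]
      if (cnt == 0L) return(NULL)
      from <- nodes[rep(seq_len(n), times = n)]
      to <- nodes[rep(seq_len(n), each = n)]
      ok <- (lvl[to] - lvl[from]) == o
      pool <- which(ok)
      if (cnt > length(pool))
        stop_invalid("infeasible edge count for order ", o, ": ",
                     cnt, " > ", length(pool))
      pick <- sort(sample(pool, cnt))
      data.frame(regulator = from[pick], target = to[pick], lag = o)
    })
    edges <- do.call(rbind, rows)
    if (is.null(edges))
      edges <- data.frame(regulator = character(0), target = character(0),
                          lag = integer(0))
    truth_network(nodes, edges, levels = lvl, surrogate = FALSE)
  })
}

# Deterministic child rule: a single parent is copied; multiple parents are
# combined with a dominant-activation gate -- elementwise max (OR-like) for
# even target indices, min (AND-like) for odd ones.  Alternating the gate
# keeps marginals away from saturation down the cascade while leaving every
# parent pairwise-informative about the child (a parity rule would make each
# parent pairwise-independent of the child and blind the optimal-lag
# restriction of the star search).
child_rule <- function(parent_states, target_index) {
  if (length(parent_states) == 1L) return(parent_states)
  if (target_index %% 2L == 0L) max(parent_states) else min(parent_states)
}

#' Static-network sampling followed by level-wise time shifting
#'
#' Draws i.i.d. time columns from a static Bayesian network over the leveled
#' truth topology (roots uniform over the `k` states; a child takes the
#' deterministic rule of its parents with probability `q`, else a uniform
#' state), then shifts the profile of every level-`l` node forward by
#' `l - 1` time units and truncates all series to the common window.  An
#' edge with level gap `o` thereby becomes an order-`o` lagged interaction.
#'
#' @param network a leveled [truth_network()].
#' @param spec a [sim_spec()].
#' @return a [time_series_set()] of `m` series with exactly `n_obs` points
#'   each, integer-valued entries in `0..k-1` (wrap with
#'   [as_discrete_dataset()] before learning).  Internally `n_obs + max
#'   shift` static columns are sampled so the shift truncation leaves the
#'   requested length.
#' @export
simulate_static_then_shift <- function(network, spec) {
  stopifnot(inherits(network, "truth_network"), inherits(spec, "sim_spec"))
  levels <- attr(network, "levels")
  if (is.null(levels)) stop_invalid("network must carry levels")
  nodes <- attr(network, "nodes")
  n <- length(nodes)
  maxshift <- max(levels) - 1L
  if (spec$n_obs <= maxshift)
    stop_invalid("n_obs must exceed the maximum level shift")
  nstat <- spec$n_obs + maxshift
  parents_of <- lapply(nodes, function(nd) network$regulator[network$target == nd])
  ord <- order(levels[nodes])  # shallower levels first: valid sampling order
  with_seed(spec$seed, {
    series <- lapply(seq_len(spec$m), function(rep_i) {
      s <- matrix(0L, n, nstat, dimnames = list(nodes, NULL))
      for (t in seq_len(nstat)) {
        for (i in ord) {
          pa <- parents_of[[i]]
          s[i, t] <- if (length(pa) == 0L || runif(1) > spec$q) {
            sample.int(spec$k, 1L) - 1L
          } else {
            child_rule(s[pa, t], i)
          }
        }
      }
      out <- matrix(0L, n, spec$n_obs, dimnames = list(nodes, NULL))
      for (i in seq_len(n)) {
        sh <- levels[nodes[i]] - 1L
        out[i, ] <- s[i, (maxshift + 1L - sh):(nstat - sh)]
      }
      out
    })
    time_series_set(series, gene_ids = nodes)
  })
}

#' Direct d-th order dynamic Bayesian network sampling
#'
#' Alternative generator that honors the lagged edges directly: the first
#' `max(lag)` slices are uniform, then each gene follows the deterministic
#' rule of its lagged parents with probability `q` (uniform otherwise).
#'
#' @param network a [truth_network()] (levels not required).
#' @param spec a [sim_spec()].
#' @return a [time_series_set()] with integer-valued entries in `0..k-1`.
#' @export
simulate_dbn <- function(network, spec) {
  stopifnot(inherits(network, "truth_network"), inherits(spec, "sim_spec"))
  nodes <- attr(network, "nodes")
  n <- length(nodes)
  maxlag <- if (nrow(network) > 0L) max(network$lag) else 1L
  if (spec$n_obs <= maxlag)
    stop_invalid("n_obs must exceed the maximum lag")
  parents_of <- lapply(nodes, function(nd) {
    e <- network[network$target == nd, , drop = FALSE]
    list(gene = match(e$regulator, nodes), lag = e$lag)
  })
  with_seed(spec$seed, {
    series <- lapply(seq_len(spec$m), function(rep_i) {
      s <- matrix(0L, n, spec$n_obs, dimnames = list(nodes, NULL))
      s[, seq_len(maxlag)] <- sample.int(spec$k, n * maxlag, replace = TRUE) - 1L
      for (t in (maxlag + 1L):spec$n_obs) {
        for (i in seq_len(n)) {
          pa <- parents_of[[i]]
          s[i, t] <- if (length(pa$gene) == 0L || runif(1) > spec$q) {
            sample.int(spec$k, 1L) - 1L
          } else {
            child_rule(s[cbind(pa$gene, t - pa$lag)], i)
          }
        }
      }
      s
    })
    time_series_set(series, gene_ids = nodes)
  })
}

#' Shuffle negative control
#'
#' Independently permutes each gene's observations within each series,
#' destroying temporal structure while preserving every per-gene value
#' multiset (and hence marginal entropies).  A learner applied to shuffled
#' data should return a (near-)empty, hub-free network.
#'
#' @param dataset a [time_series_set()] or [discrete_dataset()].
#' @param seed RNG seed.
#' @return an object of the same class as `dataset`.
#' @export
shuffle_control <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "time_series_set") ||
              inherits(dataset, "discrete_dataset"))
  series <- with_seed(seed, {
    lapply(dataset$series, function(s) {
      for (g in seq_len(nrow(s))) s[g, ] <- s[g, sample.int(ncol(s))]
      s
    })
  })
  if (inherits(dataset, "discrete_dataset")) {
    discrete_dataset(series, k = dataset$k, gene_ids = dataset$gene_ids)
  } else {
    time_series_set(series, gene_ids = dataset$gene_ids)
  }
}
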