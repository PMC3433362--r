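test_that("the search recovers a planted deterministic edge", {
  withr::with_seed(10, {
    x1 <- sample(0:1, 60, TRUE)
    x2 <- c(0L, x1[-60])
    noise <- matrix(sample(0:1, 3 * 60, TRUE), 3)
    dd <- discrete_dataset(unname(rbind(x1, x2, noise)), k = 2)
  })
  fit <- learn_parents_plus(dd, 2, d = 1, alpha = 0.999)
  expect_equal(fit$parents$gene, 1L)
  expect_equal(fit$parents$lag, 1L)
  # returned score never exceeds the empty-set score
  expect_lte(fit$score$s, 2 * fit$score$ne * shifted_entropy(dd, 2, 1) + 1e-9)
})

test_that("search equals the exhaustive oracle on seeded random instances", {
  for (seed in 1:6) {
    k <- if (seed %% 2) 2 else 3
    d <- if (seed %% 3) 1 else 2
    dd <- random_dataset(n = 4, N = 35, k = k, seed = 100 + seed)
    for (child in c(1, 3)) {
      fit <- learn_parents_plus(dd, child, d, alpha = 0.999)
      cap <- pstar_bound(fit$score$ne, k, 0.999,
                         hs = shifted_entropy(dd, child, d))$pstar
      orc <- exhaustive_oracle(dd, child, d, alpha = 0.999, max_card = cap)
      expect_equal(fit$score$s, orc$score$s, tolerance = 1e-9)
      expect_equal(fit$parents$gene, orc$parents$gene)
      expect_equal(fit$parents$lag, orc$parents$lag)
    }
  }
})

test_that("stopping rule is sound and never reaches the p* bound", {
  for (seed in 1:4) {
    dd <- random_dataset(n = 5, N = 40, k = 2, seed = 200 + seed)
    fit <- learn_parents_plus(dd, 1, d = 2, alpha = 0.999)
    tr <- fit$trace
    enum <- tr[tr$enumerated, ]
    # whenever a level was enumerated, its penalty was below the incumbent
    expect_true(all(enum$u < enum$incumbent_before))
    # no enumerated level at or beyond the numeric p* bound
    expect_true(all(enum$p < attr(tr, "pstar")))
    # subset counts are full binomial coefficients (no silent truncation)
    expect_equal(enum$n_subsets,
                 choose(attr(tr, "n_candidates"), enum$p))
  }
})

test_that("p* bound machinery reproduces worked examples and the closed form", {
  pb <- pstar_bound(20, 3, 0.999)
  expect_equal(pb$threshold, 2 * 20 * log(3))
  expect_equal(pb$pstar, 2)  # U(1)=18.47 < 43.94 <= U(2)=51.38

  expect_equal(pstar_bound(100, 3, 0.999)$closed_form, 6)

  # the closed form over-estimates the numeric p* across a grid
  for (k in 2:4) for (alpha in c(0.5, 0.9, 0.999, 0.9999)) {
    for (ne in c(5, 20, 100, 1000)) {
      pb <- pstar_bound(ne, k, alpha)
      expect_gte(pb$closed_form, pb$pstar)
    }
  }
})

test_that("optimal lag table maximizes pairwise MI with smallest-lag ties", {
  withr::with_seed(11, {
    x <- sample(0:1, 80, TRUE)
    y <- c(0L, 0L, x[1:78])          # y[t] = x[t-2]
    z <- rep(0L, 80)                 # constant
    dd <- discrete_dataset(rbind(x, y, z), k = 2)
  })
  lags <- optimal_lag_table(dd, 2, 3)
  expect_equal(unname(lags[1]), 2L)  # true lag
  expect_equal(unname(lags[3]), 1L)  # constant gene: all Is equal, smallest lag
  # d = 1: all lags are 1
  expect_true(all(optimal_lag_table(dd, 2, 1) == 1L))
})

test_that("star equals plus at d = 1 and finds the true lag at d = 3", {
  dd <- random_dataset(n = 4, N = 40, k = 2, seed = 33)
  for (child in 1:4) {
    fp <- learn_parents_plus(dd, child, 1, alpha = 0.999)
    fs <- learn_parents_star(dd, child, 1, alpha = 0.999)
    expect_equal(fp$parents, fs$parents)
    expect_equal(fp$score$s, fs$score$s, tolerance = 1e-12)
  }

  withr::with_seed(12, {
    x <- sample(0:1, 100, TRUE)
    y <- c(0L, x[-100])              # lag-1 copy
    noise <- matrix(sample(0:1, 2 * 100, TRUE), 2)
    dd2 <- discrete_dataset(unname(rbind(x, y, noise)), k = 2)
  })
  fs3 <- learn_parents_star(dd2, 2, 3, alpha = 0.999)
  expect_equal(fs3$parents$gene, 1L)
  expect_equal(fs3$parents$lag, 1L)
  # star candidate set has n candidates vs n*d for plus
  fp3 <- learn_parents_plus(dd2, 2, 3, alpha = 0.999)
  expect_equal(attr(fs3$trace, "n_candidates"), 4L)
  expect_equal(attr(fp3$trace, "n_candidates"), 12L)
})

test_that("network learning is deterministic under threads and gene permutation", {
  truth <- random_cascade_network(6, 3, c(3, 2), seed = 2)
  sim <- simulate_dbn(truth, sim_spec(q = 0.95, m = 2, n_obs = 40, k = 2, seed = 3))
  dd <- as_discrete_dataset(sim, 2)

  n1 <- learn_network(dd, d = 2, alpha = 0.999, threads = 1)
  n2 <- learn_network(dd, d = 2, alpha = 0.999, threads = 3)
  expect_identical(as_edge_list(n1), as_edge_list(n2))

  # permuting gene order relabels but does not change the learned structure
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  ddp <- discrete_dataset(lapply(dd$series, function(s) s[perm, ]), k = 2,
                          gene_ids = dd$gene_ids[perm])
  np <- learn_network(ddp, d = 2, alpha = 0.999)
  canon <- function(net) {
    e <- as_edge_list(net)
    e <- e[order(e$regulator, e$target, e$lag), c("regulator", "target", "lag")]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(np), canon(n1))
})

test_that("all-constant data yield an empty network", {
  dd <- discrete_dataset(matrix(0L, 3, 20), k = 2)
  net <- learn_network(dd, d = 1, alpha = 0.999)
  expect_equal(nrow(as_edge_list(net)), 0L)
})

test_that("raising alpha never enlarges a parent set on the same data", {
  for (seed in 1:4) {
    truth <- random_cascade_network(5, 2, c(3), seed = seed)
    sim <- simulate_dbn(truth, sim_spec(q = 0.85, m = 1, n_obs = 50, k = 2,
                                        seed = seed))
    dd <- as_discrete_dataset(sim, 2)
    for (child in 1:5) {
      lo <- learn_parents_plus(dd, child, 1, alpha = 0.999)
      hi <- learn_parents_plus(dd, child, 1, alpha = 0.9999)
      expect_lte(nrow(hi$parents), nrow(lo$parents))
    }
  }
})

test_that("oracle guard and trivial cases behave", {
  dd <- random_dataset(n = 3, N = 20, k = 2, seed = 5)
  expect_equal(nrow(exhaustive_oracle(dd, 1, 1, 0.999, max_card = 0)$parents), 0L)
  big <- random_dataset(n = 30, N = 20, k = 2, seed = 6)
  expect_error(exhaustive_oracle(big, 1, 2, 0.999, max_card = 5), "guard")

  # single candidate, deterministic copy -> that candidate
  x <- withr::with_seed(7, sample(0:1, 30, TRUE))
  y <- c(0L, x[-30])
  dd2 <- discrete_dataset(rbind(x, y), k = 2)
  orc <- exhaustive_oracle(dd2, 2, 1, 0.999, max_card = 1, allow_self = FALSE)
  expect_equal(orc$parents$gene, 1L)
})

test_that("search refuses invalid input", {
  dd <- random_dataset(n = 3, N = 20, k = 2, seed = 5)
  expect_error(learn_parents_plus(dd, 9, 1), "range")
  expect_error(learn_parents_plus(dd, 1, 0), "d")
})
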