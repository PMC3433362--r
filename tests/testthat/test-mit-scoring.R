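test_that("shifted entropy matches closed forms and the counting oracle", {
  # balanced binary column
  dd <- discrete_dataset(matrix(c(0L, rep(c(0L, 1L), 10)), 1), k = 2)
  # child column after d=1 shift is the balanced part
  expect_equal(shifted_entropy(dd, 1, 1), log(2), tolerance = 1e-12)

  # constant column
  ddc <- discrete_dataset(matrix(0L, 1, 10), k = 2)
  expect_equal(shifted_entropy(ddc, 1, 1), 0)

  # column (0,0,1,2) with k=3: -(1/2 log 1/2 + 1/4 log 1/4 + 1/4 log 1/4)
  dd3 <- discrete_dataset(matrix(c(9L, 0L, 0L, 1L, 2L), 1) * c(0L, 1L, 1L, 1L, 1L),
                          k = 3)
  expect_equal(shifted_entropy(dd3, 1, 1),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shifted_entropy(dd3, 1, 1), 1.0397, tolerance = 1e-4)
})

test_that("time-delayed MI agrees with the nested-loop contingency oracle to 1e-12", {
  expect_identical(time_delayed_mi(random_dataset(), 1, lagged_parents(), 1), 0)

  # deterministic copy: Is equals the shifted entropy of the child
  x <- withr::with_seed(2, sample(0:1, 40, TRUE))
  y <- c(0L, x[-40])
  dd <- discrete_dataset(rbind(x, y), k = 2)
  expect_equal(time_delayed_mi(dd, 2, lagged_parents(1L, 1L), 1),
               shifted_entropy(dd, 2, 1), tolerance = 1e-12)

  # random instances vs brute-force joint-count MI
  for (seed in 1:8) {
    k <- if (seed %% 2) 2 else 3
    dd <- random_dataset(n = 3, N = 18, k = k, m = if (seed %% 3) 1 else 2,
                         seed = seed)
    d <- if (seed %% 2) 1 else 2
    ps <- lagged_parents(c(1L, 3L, 2L), c(1L, d, 1L))
    al <- align_samples(dd, 2, ps, d)
    expect_equal(time_delayed_mi(dd, 2, ps, d), oracle_mi(al$child, al$parents),
                 tolerance = 1e-12)
    expect_equal(shifted_entropy(dd, 2, d), oracle_entropy(al$child),
                 tolerance = 1e-12)
  }
})

test_that("compiled pairwise/subset MI matches the R scoring path exactly", {
  for (seed in 1:5) {
    dd <- random_dataset(n = 4, N = 25, k = 3, seed = seed)
    frame <- dbnmit:::alignment_frame(dd, 2)
    child <- frame$child[, 1]
    mi_cpp <- dbnmit:::.mit_pairwise_mi(frame$lagged, child, 3L)
    cands <- data.frame(gene = rep(1:4, each = 2), lag = rep(1:2, 4))
    mi_r <- vapply(seq_len(nrow(cands)), function(j)
      time_delayed_mi(dd, 1, cands[j, ], 2), 0)
    expect_equal(mi_cpp, mi_r, tolerance = 1e-12)

    best <- dbnmit:::.mit_best_subset(frame$lagged, child, 3L, 2L)
    mi_pairs <- utils::combn(8, 2, function(ix)
      time_delayed_mi(dd, 1, cands[ix, ], 2))
    expect_equal(best$mi, max(mi_pairs), tolerance = 1e-12)
    expect_equal(best$n_evaluated, choose(8, 2))
  }
})

test_that("penalty degrees of freedom follow the sorted-state-count rule", {
  expect_equal(penalty_dof(3, c(3, 3)), c(4, 12))
  expect_equal(penalty_dof(2, c(2, 2, 2)), c(1, 2, 4))
  # mixed states: child r=3, parents r=(2,4) -> sorted (4,2): 6 then 8
  expect_equal(penalty_dof(3, c(2, 4)), c(6, 8))
  expect_equal(penalty_dof(3, integer(0)), integer(0))
  expect_error(penalty_dof(1, 2), "state counts")
})

test_that("penalty table matches an independent inverse-CDF oracle", {
  pt <- build_penalty_table(0.999, 3, 3)
  expect_equal(pt$chi_values[1], oracle_chisq_quantile(0.999, 4),
               tolerance = 1e-6)
  expect_equal(pt$chi_values[1], 18.467, tolerance = 1e-3)
  expect_equal(pt$cumulative[2],
               oracle_chisq_quantile(0.999, 4) + oracle_chisq_quantile(0.999, 12),
               tolerance = 1e-6)
  expect_equal(pt$cumulative[2], 51.376, tolerance = 1e-3)

  # strictly increasing cumulative for several (alpha, k)
  for (alpha in c(0.9, 0.999, 0.9999)) {
    for (k in 2:4) {
      cum <- build_penalty_table(alpha, k, 6)$cumulative
      expect_true(all(diff(cum) > 0))
    }
  }
  expect_error(build_penalty_table(1.2, 3), "alpha")
  expect_error(build_penalty_table(0.999, 2, max_p = 40), "guard")
})

test_that("parent-set scores decompose as s = v + u and match raw-count recomputation", {
  dd <- random_dataset(n = 3, N = 30, k = 2, seed = 9)
  ne <- effective_observations(dd, 1)

  sc0 <- parent_set_score(dd, 1, lagged_parents(), 1, alpha = 0.999)
  expect_equal(sc0$u, 0)
  expect_equal(sc0$s, 2 * ne * shifted_entropy(dd, 1, 1), tolerance = 1e-12)

  # deterministic copy parent: v'' = 0, s = chi_{alpha,(k-1)^2}
  x <- withr::with_seed(2, sample(0:1, 40, TRUE))
  y <- c(0L, x[-40])
  ddc <- discrete_dataset(rbind(x, y), k = 2)
  scc <- parent_set_score(ddc, 2, lagged_parents(1L, 1L), 1, alpha = 0.999)
  expect_equal(scc$v, 0, tolerance = 1e-9)
  expect_equal(scc$s, stats::qchisq(0.999, 1), tolerance = 1e-9)

  # arbitrary instance vs independent recomputation from raw counts
  ps <- lagged_parents(c(2L, 3L), c(1L, 1L))
  sc <- parent_set_score(dd, 1, ps, 1, alpha = 0.999)
  al <- align_samples(dd, 1, ps, 1)
  v_or <- 2 * ne * (oracle_entropy(al$child) - oracle_mi(al$child, al$parents))
  u_or <- oracle_chisq_quantile(0.999, 1) + oracle_chisq_quantile(0.999, 2)
  expect_equal(sc$s, v_or + u_or, tolerance = 1e-6)
  expect_identical(sc$s, sc$v + sc$u)
})

test_that("MI is monotone in the parent set and bounded by entropies", {
  for (seed in 1:6) {
    dd <- random_dataset(n = 4, N = 25, k = 2, seed = seed)
    hs <- shifted_entropy(dd, 1, 2)
    base <- lagged_parents(c(2L, 3L), c(1L, 2L))
    mi_base <- time_delayed_mi(dd, 1, base, 2)
    expect_gte(mi_base, -1e-12)
    expect_lte(mi_base, hs + 1e-12)
    expect_lte(hs, log(dd$k) + 1e-12)
    for (extra in list(c(4L, 1L), c(1L, 1L), c(4L, 2L))) {
      bigger <- lagged_parents(c(base$gene, extra[1]), c(base$lag, extra[2]))
      expect_gte(time_delayed_mi(dd, 1, bigger, 2), mi_base - 1e-12)
    }
  }
})

test_that("penalty depends only on cardinality under variable uniformity", {
  dd <- random_dataset(n = 5, N = 30, k = 3, seed = 4)
  sets <- list(lagged_parents(c(1L, 2L), c(1L, 1L)),
               lagged_parents(c(4L, 5L), c(2L, 1L)),
               lagged_parents(c(3L, 1L), c(2L, 2L)))
  us <- vapply(sets, function(ps)
    parent_set_score(dd, 2, ps, 2, alpha = 0.999)$u, 0)
  expect_true(all(abs(us - us[1]) < 1e-12))
  u1 <- parent_set_score(dd, 2, sets[[1]][1, ], 2, alpha = 0.999)$u
  expect_lt(u1, us[1])
})

test_that("network score orderings are equivalent (max form vs min form)", {
  dd <- random_dataset(n = 4, N = 30, k = 2, seed = 12)
  nets <- list(
    dbn_network(list(lagged_parents(2L, 1L), lagged_parents(),
                     lagged_parents(c(1L, 2L), c(1L, 2L)), lagged_parents()),
                d = 2, gene_ids = dd$gene_ids),
    dbn_network(list(lagged_parents(), lagged_parents(3L, 2L),
                     lagged_parents(), lagged_parents(1L, 1L)),
                d = 2, gene_ids = dd$gene_ids),
    dbn_network(rep(list(lagged_parents()), 4), d = 2,
                gene_ids = dd$gene_ids))
  sc <- lapply(nets, function(g) network_score(dd, g, 2, alpha = 0.999))
  # empty network: S'' = 0
  expect_equal(sc[[3]]$s_mit_max, 0)
  # constant linking the two forms: sum_i 2 Ne Hs(X_i)
  ne <- effective_observations(dd, 2)
  const <- sum(vapply(1:4, function(i) 2 * ne * shifted_entropy(dd, i, 2), 0))
  for (s in sc) expect_equal(s$s_mit_min + s$s_mit_max, const, tolerance = 1e-9)
  # ordering equivalence on every pair
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sc[[i]]$s_mit_max >= sc[[j]]$s_mit_max,
                 sc[[i]]$s_mit_min <= sc[[j]]$s_mit_min)
  }
})

test_that("single-edge deterministic network scores 2*Ne*Hs - chi", {
  x <- withr::with_seed(2, sample(0:1, 40, TRUE))
  y <- c(0L, x[-40])
  dd <- discrete_dataset(rbind(x, y), k = 2)
  net <- dbn_network(list(lagged_parents(), lagged_parents(1L, 1L)),
                     d = 1, gene_ids = dd$gene_ids)
  sc <- network_score(dd, net, 1, alpha = 0.999)
  ne <- effective_observations(dd, 1)
  expect_equal(sc$s_mit_max, 2 * ne * shifted_entropy(dd, 2, 1) -
                 stats::qchisq(0.999, 1), tolerance = 1e-9)
  expect_error(network_score(dd, net, 0), "d")
})

test_that("general (non-uniform) penalty is available for scoring only", {
  # three genes where gene 3 only ever uses 2 of 3 states
  mat <- withr::with_seed(8, rbind(sample(0:2, 30, TRUE), sample(0:2, 30, TRUE),
                                   sample(0:1, 30, TRUE)))
  dd <- discrete_dataset(mat, k = 3)
  net <- dbn_network(list(lagged_parents(), lagged_parents(),
                          lagged_parents(c(1L, 2L), c(1L, 1L))),
                     d = 1, gene_ids = dd$gene_ids)
  uni <- network_score(dd, net, 1, alpha = 0.999)
  gen <- network_score(dd, net, 1, alpha = 0.999, assume_uniform = FALSE)
  # child r=2, parents r=(3,3): dof (2,6) vs uniform (4,12)
  expect_equal(gen$nodes$u[3],
               sum(stats::qchisq(0.999, penalty_dof(2, c(3, 3)))),
               tolerance = 1e-9)
  expect_lt(gen$nodes$u[3], uni$nodes$u[3])
})
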