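# Independent oracles for the scoring machinery, deliberately written as
# naive nested-loop contingency code with no shared machinery with the
# package internals.

# Plug-in entropy by explicit counting.
oracle_entropy <- function(x) {
  vals <- unique(x)
  n <- length(x)
  h <- 0
  for (v in vals) {
    cnt <- 0
    for (xi in x) if (identical(xi, v)) cnt <- cnt + 1
    p <- cnt / n
    h <- h - p * log(p)
  }
  h
}

# Joint mutual information between y and the columns of mat, by brute-force
# contingency counting over all observed configurations.
oracle_mi <- function(y, mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  if (ncol(mat) == 0) return(0)
  n <- length(y)
  keys <- apply(mat, 1, paste, collapse = "|")
  ukeys <- unique(keys)
  uy <- unique(y)
  mi <- 0
  for (kk in ukeys) {
    nk <- sum(keys == kk)
    for (vy in uy) {
      nky <- 0
      for (r in seq_len(n)) if (keys[r] == kk && y[r] == vy) nky <- nky + 1
      if (nky > 0) {
        ny <- sum(y == vy)
        mi <- mi + (nky / n) * log((nky / n) / ((nk / n) * (ny / n)))
      }
    }
  }
  mi
}

# Chi-square quantile by numeric inversion of the regularized incomplete
# gamma function (independent of stats::qchisq).
oracle_chisq_quantile <- function(alpha, df) {
  stats::uniroot(function(q) stats::pgamma(q / 2, shape = df / 2) - alpha,
                 lower = 0, upper = 10 * df + 200, tol = 1e-10)$root
}

# Manual lag-aware alignment for a single series (matrix genes x N), used to
# cross-check align_samples.
oracle_align <- function(mat, child, parents, d) {
  n_t <- ncol(mat)
  rows <- list()
  for (t in (d + 1):n_t) {
    row <- c(mat[child, t],
             if (nrow(parents) > 0)
               mapply(function(g, l) mat[g, t - l], parents$gene, parents$lag))
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

# Random small discrete dataset.
random_dataset <- function(n = 4, N = 30, k = 2, m = 1, seed = 1) {
  withr::with_seed(seed, {
    series <- lapply(seq_len(m), function(i)
      matrix(sample(0:(k - 1), n * N, replace = TRUE), n, N))
    discrete_dataset(series, k = k)
  })
}
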