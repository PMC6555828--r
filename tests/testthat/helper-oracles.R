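# Independent oracles used across the suite.

# Exhaustive grid-search MLE for a two-component binomial mixture:
# maximizes sum_k c_k * log(w * B(k; n, p1) + (1 - w) * B(k; n, p2)) over
# w, p1 < p2 on a regular grid. Brute force, independent of the EM path.
grid_binom_mixture <- function(k, n_units, step = 0.01) {
  counts <- tabulate(k + 1L, nbins = n_units + 1L)
  ks <- 0:n_units
  p_grid <- seq(0, 1, by = step)
  w_grid <- seq(0, 1, by = step)
  pmf <- vapply(p_grid, function(p) dbinom(ks, n_units, p), numeric(n_units + 1L))
  best <- list(loglik = -Inf)
  for (i in seq_along(p_grid)) {
    for (j in seq_along(p_grid)) {
      if (p_grid[j] <= p_grid[i]) next
      # mixture pmf for every w at once: (n+1) x length(w_grid)
      M <- outer(pmf[, i], w_grid) + outer(pmf[, j], 1 - w_grid)
      M[M <= 0] <- .Machine$double.xmin
      ll <- colSums(counts * log(M))
      m <- which.max(ll)
      if (ll[m] > best$loglik)
        best <- list(loglik = ll[m], w = w_grid[m],
                     p1 = p_grid[i], p2 = p_grid[j])
    }
  }
  best
}

# Grid-search single-binomial MLE over p (independent of the closed form).
grid_binom_p <- function(k, n_units, step = 1e-4) {
  p_grid <- seq(step, 1 - step, by = step)
  ll <- vapply(p_grid, function(p) sum(dbinom(k, n_units, p, log = TRUE)),
               numeric(1))
  p_grid[which.max(ll)]
}

# Mean and SD of a mixture of scaled binomials k/n (analytic).
binom_mixture_moments <- function(n_units, weights, ps) {
  m <- ps
  v <- ps * (1 - ps) / n_units
  mu <- sum(weights * m)
  var <- sum(weights * (v + m^2)) - mu^2
  list(mean = mu, var = var)
}

# Brute-force median of a base-10 log-normal mixture by scanning the CDF on
# a fine log10 grid.
scan_mixture_median <- function(w, mu, sigma, n_grid = 1e6) {
  lo <- min(mu - 8 * sigma); hi <- max(mu + 8 * sigma)
  l <- seq(lo, hi, length.out = n_grid)
  cdf <- Reduce(`+`, lapply(seq_along(w),
                            function(i) w[i] * pnorm(l, mu[i], sigma[i])))
  10^l[which.max(cdf >= 0.5)]
}
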