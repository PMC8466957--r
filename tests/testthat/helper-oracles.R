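# Brute-force enumeration oracles, independent of the implementation paths
# they check. Feasible only at tiny n; that is the point.

# two-sided exact Mann-Whitney p: enumerate all C(n+m, n) group assignments
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  m <- length(pooled)
  combos <- utils::combn(m, n)
  us <- apply(combos, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: distance of U from its null mean
  mu <- n * (m - n) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided exact Wilcoxon signed-rank p: enumerate all 2^m sign patterns
# of the nonzero differences
signrank_enum_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided exact Spearman permutation p by full enumeration
spearman_enum <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perm_rows <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- perm_rows(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
  }
  pm <- perm_rows(length(x))
  rhos <- apply(pm, 1L, function(idx) stats::cor(rx, ry[idx]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# two-sided Fisher exact p for a 2x2 table: enumerate the hypergeometric
# support, summing probabilities <= that of the observed table
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); N <- sum(tab)
  support <- max(0L, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, N - r1, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo polygon area by point-in-polygon rejection sampling
mc_polygon_area <- function(poly, n_points = 1e6, seed = 42L) {
  set.seed(seed)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  xs <- runif(n_points, xr[1L], xr[2L])
  ys <- runif(n_points, yr[1L], yr[2L])
  mean(points_in_polygon(poly, xs, ys)) * diff(xr) * diff(yr)
}

# small default config for image tests: full raster keeps runtimes modest
test_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, ...)
}
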