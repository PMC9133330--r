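# Independent brute-force oracles used to verify the package's statistics.

# Fisher's exact test by direct enumeration of all 2x2 tables with the
# observed margins (hypergeometric probabilities).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(xs, r1, r2, c1)
  obs <- tab[1, 1]
  p_obs <- stats::dhyper(obs, r1, r2, c1)
  dir_greater <- tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]
  one <- if (dir_greater) sum(pr[xs >= obs]) else sum(pr[xs <= obs])
  two <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  list(one_sided = one, two_sided = two)
}

# Exact Mann-Whitney null distribution by enumerating group assignments of
# the pooled values; U computed from the pair-count definition
# #(x > y) + 0.5 #(x == y), independent of the rank-sum route.
oracle_mw <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_pairs <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_pairs(x, y)
  idx <- utils::combn(length(pool), n1)
  u_all <- apply(idx, 2L, function(i) u_pairs(pool[i], pool[-i]))
  mu <- n1 * (length(pool) - n1) / 2
  eps <- 1e-9
  list(u1 = u_obs,
       p_less = mean(u_all <= u_obs + eps),
       p_greater = mean(u_all >= u_obs - eps),
       p_two = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps))
}

# Tail probability of a sum of independent Bernoullis by complete
# enumeration of all 2^n outcomes (tiny n only).
oracle_poisbin_tail <- function(p, k) {
  n <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1L, function(g) prod(ifelse(g == 1, p, 1 - p)))
  sum(pr[rowSums(grid) >= k])
}

# Flat single-band norm tables in z units, for classifying standardized
# synthetic scores at a stated percentile.
z_norms <- function(measures, percentile) {
  norm_table(data.frame(
    measure = measures, band_lo = 0L, band_hi = 1200L,
    cutoff = stats::qnorm(percentile / 100), percentile = percentile,
    worse = "lower"))
}
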