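# Independent oracles used by unit and acceptance tests. All are brute-force
# combinatorial computations kept deliberately separate from the package's
# code paths (choose() sums and permutation enumeration, no dhyper/phyper).

hyper_tail_oracle <- function(N, M, n, m) {
  k <- seq(m, min(M, n))
  if (length(k) == 0 || m > min(M, n)) return(0)
  sum(choose(M, k) * choose(N - M, n - k)) / choose(N, n)
}

fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(m, k)
  if (lo > hi || m + n2 == 0) return(1)
  xs <- lo:hi
  pr <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  p_obs <- choose(m, a) * choose(n2, k - a) / choose(m + n2, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-07)]))
}

# full permutation enumeration of the two-sided Mann-Whitney p-value
wilcox_perm_oracle <- function(x, y) {
  m <- length(x); N <- m + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(N, m)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  if (u_obs > mu) {
    min(1, 2 * mean(us >= u_obs))
  } else {
    min(1, 2 * mean(us <= u_obs))
  }
}

spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
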