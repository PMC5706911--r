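# Shared statistical primitives: hypergeometric enrichment, exact 2x2
# Fisher test, Benjamini-Hochberg adjustment, Wilcoxon rank-sum, Spearman.
#
# The 2x2 exact test is implemented directly on top of dhyper() rather than
# stats::fisher.test: the two-sided convention (sum the probabilities of all
# tables whose point probability does not exceed the observed one) is the
# same, but this version is two orders of magnitude faster, which matters
# for the exhaustive oracle checks and the permutation-style screens.

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing `m` or more query hits in an annotation term,
#' \eqn{P(X \ge m)} for \eqn{X \sim \mathrm{Hypergeom}(N, M, n)}: a universe
#' of `N` genes of which `M` belong to the term, with a query set of size
#' `n` containing `m` term members.
#'
#' @param N universe size.
#' @param M number of universe genes in the term.
#' @param n query-set size.
#' @param m number of query genes in the term.
#' @return p-value in (0, 1]. Vectorized over its arguments.
#' @examples
#' hypergeom_enrich(10, 4, 5, 4) # 6/252
#' @export
hypergeom_enrich <- function(N, M, n, m) {
  bad <- !is.finite(N) | !is.finite(M) | !is.finite(n) | !is.finite(m) |
    N < 0 | M < 0 | n < 0 | m < 0 | M > N | n > N | m > pmin(M, n)
  if (any(bad)) {
    ctl_stop("inconsistent hypergeometric counts (need 0 <= m <= min(M, n), M <= N, n <= N)",
             "domain_error")
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all tables
#' whose point probability is at most that of the observed table (the
#' convention of \code{stats::fisher.test}, including its relative-error
#' guard for floating-point ties).
#'
#' @param a,b,c,d cell counts of the table \code{rbind(c(a, b), c(c, d))}
#'   (rows = groups, columns = outcome present/absent).
#' @return list with `p.value`, `odds.ratio` (sample OR, \eqn{ad/bc}),
#'   `odds.ratio.haldane` (all cells + 0.5, finite with zero cells) and the
#'   `table`.
#' @examples
#' fisher_exact_2x2(0, 10, 10, 0)$p.value # 2 / choose(20, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells) | cells < 0 | cells != round(cells))) {
    ctl_stop("2x2 table cells must be non-negative integers", "domain_error")
  }
  m <- a + b          # row-1 total
  n2 <- c + d         # row-2 total
  k <- a + c          # column-1 total
  lo <- max(0L, k - n2)
  hi <- min(m, k)
  if (lo > hi || m + n2 == 0) {
    p <- 1
  } else {
    support <- lo:hi
    dens <- stats::dhyper(support, m, n2, k)
    d_obs <- stats::dhyper(a, m, n2, k)
    p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-07)]))
  }
  or <- (a * d) / (b * c)
  list(
    p.value = p,
    odds.ratio = or,
    odds.ratio.haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
    table = matrix(c(a, c, b, d), 2, 2)
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement and a cap at 1;
#' input order is preserved. Input p-values must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    ctl_stop("p-values must lie in (0, 1]", "domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when the combined sample size permits it: full
#' permutation enumeration over all group assignments for combined n at most
#' `enum_max` (valid with ties, using mid-ranks), the closed-form
#' Mann-Whitney distribution for tie-free samples up to `exact_max`.
#' Otherwise a tie-corrected normal approximation with a signed continuity
#' correction (so two identical samples give exactly p = 1 in any branch).
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max largest combined n for the tie-free exact null.
#' @param enum_max largest combined n for full permutation enumeration.
#' @return list with `statistic` (U for `x`), `p.value`, `exact` flag.
#' @examples
#' wilcox_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value # 0.1
#' @export
wilcox_rank_sum <- function(x, y, exact_max = 20L, enum_max = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    ctl_stop("both groups must be non-empty", "domain_error")
  }
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if ((m + n) <= enum_max) {
    us <- apply(utils::combn(m + n, m), 2, function(ix)
      sum(r[ix])) - m * (m + 1) / 2
    p <- if (u > m * n / 2) {
      min(1, 2 * mean(us >= u))
    } else {
      min(1, 2 * mean(us <= u))
    }
    return(list(statistic = u, p.value = p, exact = TRUE))
  }
  if (!has_ties && (m + n) <= exact_max) {
    p <- if (u > m * n / 2) {
      min(1, 2 * stats::pwilcox(u - 1, m, n, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::pwilcox(u, m, n))
    }
    return(list(statistic = u, p.value = p, exact = TRUE))
  }
  N <- m + n
  mu <- m * n / 2
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  # continuity correction in the direction of the deviation (sign(0) = 0,
  # so identical samples still give exactly p = 1)
  z <- u - mu - sign(u - mu) * 0.5
  p <- if (sigma2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(statistic = u, p.value = p, exact = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    ctl_stop("need two equal-length vectors of length >= 3", "domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ctl_stop("Spearman correlation undefined for a constant vector", "domain_error")
  }
  stats::cor(x, y, method = "spearman")
}
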