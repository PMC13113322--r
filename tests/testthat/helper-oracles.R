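# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms.

# Capped-Voronoi oracle: every pixel scanned against every seed; nearest seed
# within radius wins, ties to the smaller seed id.
capped_voronoi_oracle <- function(seeds, shape, radius_px) {
  nr <- shape[1]; nc <- shape[2]
  lab <- matrix(0L, nr, nc)
  for (row in seq_len(nr)) {
    for (col in seq_len(nc)) {
      px <- col - 1L; py <- row - 1L
      d2 <- (seeds$x - px)^2 + (seeds$y - py)^2
      j <- which(d2 == min(d2))[1]  # seeds ordered by id: first min = smallest id
      if (d2[j] <= radius_px^2) lab[row, col] <- seeds$id[j]
    }
  }
  lab
}

# Exact two-sided rank-sum p by enumeration over all C(m+n, m) group
# assignments (no ties assumed); same two-sided rule as the distribution
# path: 2 * min(P(U <= u), P(U >= u)), capped at 1.
ranksum_enum_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- colSums(combos) - m * (m + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Fisher two-sided p by full hypergeometric enumeration with the
# probability-mass rule (relative tolerance 1e-7, as in fisher.test).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, N - r1, c1)
  p_obs <- stats::dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Greedy matching of detected seeds to true centroids within a pixel radius.
match_seeds <- function(seeds, truth, max_dist = 3) {
  d2 <- outer(seeds$x, truth$x, "-")^2 + outer(seeds$y, truth$y, "-")^2
  list(precision = mean(apply(d2, 1, min) <= max_dist^2),
       recall = mean(apply(d2, 2, min) <= max_dist^2),
       nearest = apply(d2, 1, which.min),
       matched = apply(d2, 1, min) <= max_dist^2)
}

# Adjusted Rand index (mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
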