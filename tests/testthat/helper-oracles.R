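# Independent oracles, written straight from the published definitions and
# kept free of the package's implementation paths.

# Straight-line TMM: weighted trimmed mean of M-values of sample `obs`
# against sample `ref`, then all factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, ref_col) {
  N <- colSums(counts)
  f <- rep(1, ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref_col) next
    y <- counts[, j]; r <- counts[, ref_col]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    M <- log2((y / N[j]) / (r / N[ref_col]))
    A <- 0.5 * log2((y / N[j]) * (r / N[ref_col]))
    w <- 1 / ((N[j] - y) / (N[j] * y) + (N[ref_col] - r) / (N[ref_col] * r))
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }
  f / exp(mean(log(f)))
}

# NB log-likelihood of a 2-group one-way layout at group log-means (b1, b2)
# on the offset scale. Groups: logical vector `is_g2`.
oracle_nb_ll <- function(y, is_g2, offsets, phi, b1, b2) {
  mu <- exp(offsets + ifelse(is_g2, b2, b1))
  if (phi > 0) {
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  } else {
    sum(dpois(y, mu, log = TRUE))
  }
}

# Brute-force 2-D likelihood grid with staged refinement; returns the
# maximizing (b1, b2) and the maximized log-likelihood.
oracle_nb_grid2 <- function(y, is_g2, offsets, phi,
                            span = 4, stages = 4L, npts = 41L) {
  c1 <- log(pmax(sum(y[!is_g2]), 0.5) / sum(exp(offsets[!is_g2])))
  c2 <- log(pmax(sum(y[is_g2]), 0.5) / sum(exp(offsets[is_g2])))
  lo1 <- c1 - span; hi1 <- c1 + span
  lo2 <- c2 - span; hi2 <- c2 + span
  for (s in seq_len(stages)) {
    g1 <- seq(lo1, hi1, length.out = npts)
    g2 <- seq(lo2, hi2, length.out = npts)
    # the 2-D grid separates into two 1-D profiles for a one-way layout
    ll1 <- vapply(g1, function(b) oracle_nb_ll(y[!is_g2], logical(sum(!is_g2)),
                                               offsets[!is_g2], phi, b, 0), 0)
    ll2 <- vapply(g2, function(b) oracle_nb_ll(y[is_g2], !logical(sum(is_g2)),
                                               offsets[is_g2], phi, 0, b), 0)
    i1 <- which.max(ll1); i2 <- which.max(ll2)
    st1 <- g1[2] - g1[1]; st2 <- g2[2] - g2[1]
    b1 <- g1[i1]; b2 <- g2[i2]
    lo1 <- b1 - 2 * st1; hi1 <- b1 + 2 * st1
    lo2 <- b2 - 2 * st2; hi2 <- b2 + 2 * st2
  }
  list(b1 = b1, b2 = b2,
       loglik = oracle_nb_ll(y, is_g2, offsets, phi, b1, b2))
}

# 1-D brute-force grid for the reduced (common-mean) model.
oracle_nb_grid1 <- function(y, offsets, phi, span = 4, stages = 4L,
                            npts = 41L) {
  c0 <- log(pmax(sum(y), 0.5) / sum(exp(offsets)))
  lo <- c0 - span; hi <- c0 + span
  for (s in seq_len(stages)) {
    g <- seq(lo, hi, length.out = npts)
    ll <- vapply(g, function(b) oracle_nb_ll(y, logical(length(y)),
                                             offsets, phi, b, 0), 0)
    i <- which.max(ll)
    st <- g[2] - g[1]
    b <- g[i]
    lo <- b - 2 * st; hi <- b + 2 * st
  }
  list(b = b, loglik = oracle_nb_ll(y, logical(length(y)), offsets, phi, b, 0))
}

# Hypergeometric tail P(X >= a) by direct summation of binomial coefficients.
oracle_hyper_tail <- function(a, n, K, N) {
  supp <- seq(max(0L, n + K - N), min(n, K))
  ks <- supp[supp >= a]
  if (!length(ks)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Assignment of a read under the minimal-Hamming-distance rule, by direct
# all-pairs distance computation.
oracle_hamming1_assign <- function(read, guides) {
  d <- vapply(guides, function(g) {
    sum(utf8ToInt(read) != utf8ToInt(g))
  }, 0L)
  dmin <- min(d)
  if (dmin > 1L) return(NA_integer_)           # unmatched
  hits <- which(d == dmin)
  if (length(hits) == 1L) hits else -1L        # -1 = ambiguous
}
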