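# Independent oracles used across the suite.  These deliberately take the
# slow, literal route so they share no code path with the implementation.

# two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins, summing hypergeometric probabilities <= P(observed)
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  logp <- function(x) lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  p_obs <- logp(a)
  xs <- lo:hi
  sum(exp(logp(xs))[logp(xs) <= p_obs + 1e-7])
}

# topological overlap by explicit per-pair summation
oracle_tom <- function(adj) {
  a <- adj; diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# signed KS connectivity by brute force over all rank thresholds r: the
# maximal excess (and deficit) of the query ECDF against the uniform ECDF
oracle_ks <- function(ranks_of_query, n) {
  t <- length(ranks_of_query)
  a <- -Inf; b <- -Inf
  for (r in seq_len(n)) {
    a <- max(a, sum(ranks_of_query <= r) / t - r / n)
    b <- max(b, r / n - sum(ranks_of_query < r) / t)
  }
  if (a > b) a else -b
}

# two-sample KS statistic D by explicit ECDF-gap maximization
oracle_ks_two_sample_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# per-position PSSM rescoring, one position at a time, no vectorization
oracle_scan <- function(seq, pwm, background, thr_fraction) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(pwm)
  expect <- colSums(pwm * background)
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  thr <- smin + thr_fraction * (smax - smin)
  hits <- integer(0); scores <- numeric(0)
  for (pos in seq_len(length(bases) - L + 1)) {
    s <- 0
    for (k in seq_len(L)) {
      b <- bases[pos + k - 1]
      s <- s + if (b %in% rownames(pwm)) pwm[b, k] else expect[k]
    }
    if (s >= thr - 1e-12) {
      hits <- c(hits, pos - 1L); scores <- c(scores, unname(s))
    }
  }
  list(start0 = hits, score = scores)
}

# BH step-up applied literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# small toy expression study with two planted blocks
toy_block_study <- function(n_per = 25, n_noise = 10, n_samples = 40,
                            rho = 0.8, seed = 42) {
  withr::with_seed(seed, {
    f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
    block <- function(f, k) t(sapply(seq_len(k), function(i)
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples)))
    mat <- rbind(block(f1, n_per), block(f2, n_per))
    if (n_noise > 0)
      mat <- rbind(mat, matrix(rnorm(n_noise * n_samples), n_noise))
    dimnames(mat) <- list(sprintf("t%03d", seq_len(nrow(mat))),
                          sprintf("s%02d", seq_len(n_samples)))
    mat
  })
}
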