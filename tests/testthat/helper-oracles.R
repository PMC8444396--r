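# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (full enumeration, closed-form normal equations)
# and stay independent of the code paths they check.

# Hardy-Weinberg exact test by full enumeration: probability of every
# heterozygote configuration compatible with the allele counts, via
# exact log-factorials, summing the tail of configurations no more
# probable than the observed one (same tie rule as the implementation).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq.int(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- sapply(hets, function(h) {
    hom_a <- (n_a - h) / 2
    hom_b <- n - h - hom_a
    lfactorial(n) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  })
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_ab, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# OLS via explicit normal equations (XtX)^-1 Xt y with residual-based
# standard errors and two-sided t probabilities.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  t <- beta / se
  list(beta = drop(beta), se = se,
       p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}

# One-sided (enrichment) Fisher P by explicit hypergeometric summation.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  ks <- max(0, k - n_):min(k, m)
  probs <- choose(m, ks) * choose(n_, k - ks) / choose(m + n_, k)
  sum(probs[ks >= a])
}

# Benjamini-Hochberg by the literal step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m / i * p[ord[i]])
    adj[ord[i]] <- prev
  }
  pmin(adj, 1)
}

# Adjusted Rand index between two partitions.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_idx - expected)
}
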