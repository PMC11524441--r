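# Independent brute-force oracles. These deliberately avoid the code paths
# they check: explicit loops, textbook formulas, full enumeration.

# Point probability of a 2x2 table with fixed margins, by the factorial
# formula p = m! n! k! l! / (N! a! b! c! d!).
oracle_table_prob <- function(a, b, c, d) {
  exp(lgamma(a + b + 1) + lgamma(c + d + 1) + lgamma(a + c + 1) +
      lgamma(b + d + 1) - lgamma(a + b + c + d + 1) -
      lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) - lgamma(d + 1))
}

# Fisher exact p by full enumeration of every table with the observed
# margins. two.sided follows the minimum-likelihood rule.
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    oracle_table_prob(x, m - x, k - x, n - k + x), numeric(1))
  p_obs <- probs[xs == a]
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[xs >= a]),
              less = sum(probs[xs <= a]))
  min(1, p)
}

# Cosine similarity by explicit loop over shared gene names.
oracle_cosine <- function(u, v) {
  shared <- intersect(names(u), names(v))
  num <- 0; su <- 0; sv <- 0
  for (g in shared) {
    num <- num + u[[g]] * v[[g]]
    su <- su + u[[g]]^2
    sv <- sv + v[[g]]^2
  }
  num / sqrt(su * sv)
}

# Average ranks computed by hand (mean rank over tied positions).
oracle_ranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# Spearman rho as the explicit covariance formula on average ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Benjamini-Hochberg by the literal step-up definition:
# adj_(i) = min_{j >= i} ( n * p_(j) / j ), capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Textbook pooled-variance Student t-test.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Textbook Welch t-test with Welch-Satterthwaite degrees of freedom.
oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
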