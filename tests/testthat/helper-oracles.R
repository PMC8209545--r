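# Independent oracles and tiny fixtures shared across the suite. The oracles
# deliberately use direct definitions (enumeration, residual algebra), not the
# package's code paths.

# Benjamini-Hochberg step-up by literal definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher exact p by full enumeration of tables with fixed margins,
# probability-mass ordering.
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (n == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  a_all <- lo:hi
  probs <- dhyper(a_all, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail by explicit summation.
hyper_tail_brute <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(dhyper(k:hi, K, N - K, n))
}

# Partial-correlation t test of cor(x, y | Z): correlate residuals of x ~ Z
# and y ~ Z, then t = r sqrt(df) / sqrt(1 - r^2) with df = n - rank(Z) - 1.
partial_cor_t <- function(x, y, z) {
  z <- as.matrix(z)
  rx <- stats::lm.fit(z, x)$residuals
  ry <- stats::lm.fit(z, y)$residuals
  r <- stats::cor(rx, ry)
  df <- length(x) - qr(z)$rank - 1L
  tt <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# Orthogonal-Procrustes residual: align Y to X by translation + rotation or
# reflection (no scaling) and return the root-mean-square residual.
procrustes_error <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(mean((yc %*% rot - xc)^2))
}

# 3-gene x 4-sample toy count matrix with mixed biotypes.
tiny_counts <- function() {
  m <- matrix(c(10L, 20L, 15L, 25L,
                0L,  1L,  0L,  2L,
                100L, 90L, 110L, 95L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  count_matrix(m, c("mRNA", "lncRNA", "miRNA"))
}

tiny_design <- function() {
  sample_design(data.frame(
    sample_id = paste0("s", 1:4),
    experiment_set = "hypoxia_set",
    condition = rep(c("std_48h", "hpx_48h"), 2),
    placenta_id = rep(c("P1", "P2"), each = 2),
    batch_id = "B1", stringsAsFactors = FALSE))
}
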