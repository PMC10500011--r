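# Internal numeric helpers shared across modules.

# Rowwise Welch two-sample t: x is features x samples, idx1/idx2 column indices.
# Returns list(mean1, mean2, t, df, p). Zero-variance rows: t = 0 / p = 1 when
# the means agree, +-Inf / p = 0 otherwise.
row_welch_t <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  if (any(zero)) {
    same <- zero & (m1 == m2)
    tt[same] <- 0; p[same] <- 1; df[same] <- n1 + n2 - 2
    diffr <- zero & (m1 != m2)
    tt[diffr] <- sign(m1[diffr] - m2[diffr]) * Inf
    p[diffr] <- 0; df[diffr] <- n1 + n2 - 2
  }
  list(mean1 = m1, mean2 = m2, t = tt, df = df, p = p)
}

# Two-level label vector -> list(levels, idx1, idx2); levels ordered by first
# occurrence so "group 1" is whichever label appears first.
two_groups <- function(labels, n = length(labels)) {
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length does not match sample count")
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly 2 groups required, got ", length(lev))
  list(levels = lev, idx1 = which(labels == lev[1]), idx2 = which(labels == lev[2]))
}

# Deterministic child seeds below 2^31, derived from one global seed.
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Population (divide by n) z-scoring of matrix rows; constant rows -> 0.
zscore_rows <- function(x, warn_constant = FALSE) {
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  const <- s == 0
  if (any(const) && warn_constant)
    warning(sum(const), " constant feature(s) set to all-zero")
  s[const] <- 1
  z <- (x - m) / s
  z[const, ] <- 0
  z
}
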