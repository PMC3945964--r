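# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Closed-form K2P from transition/transversion proportions.
k2p_oracle <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# Quadratic-space Gotoh local alignment (Smith-Waterman with affine gaps);
# a gap of length L costs open + L * extend.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive FP/FN scan over pair lists.
scan_oracle <- function(d_con, d_het, thresholds) {
  data.frame(threshold = thresholds,
             fp = vapply(thresholds, function(t) sum(d_con > t), 0L + 0),
             fn = vapply(thresholds, function(t) sum(d_het <= t), 0L + 0))
}

# Row-argmin nearest-neighbour oracle over a plain distance matrix.
nn_oracle <- function(qid, m, species_of) {
  d <- m[qid, setdiff(colnames(m), qid)]
  d[is.na(d)] <- Inf
  nearest <- names(d)[round(d, 10) == min(round(d, 10))]
  unique(unname(species_of[nearest]))
}

# Pairwise Duncan comparisons: groups i, j (positions in the sorted-by-mean
# order) differ when |mi - mj| >= q((1-alpha)^(p-1), p, df) * sqrt(MSE/n_h),
# p the number of means spanned.
duncan_pairwise_oracle <- function(groups, alpha = 0.05) {
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  sizes <- vapply(groups, length, 0L)
  df <- sum(sizes) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  n_h <- k / sum(1 / sizes)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  out <- matrix(FALSE, k, k, dimnames = list(names(groups)[ord], names(groups)[ord]))
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      crit <- qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / n_h)
      out[i, j] <- out[j, i] <- (m[i] - m[j]) >= crit
    }
  }
  out
}
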