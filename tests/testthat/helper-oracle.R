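# Independent brute-force reference for the entropy estimator.
# Deliberately naive: explicit loops everywhere, no shared code with the
# package internals, so it can serve as an oracle for the vectorized path.
oracle_mm_mdisten <- function(mat, m = 3, tau = 1, r_coeff = 0.2, n = 2,
                              B = 64, s = 1) {
  nch <- nrow(mat)
  N <- ncol(mat)
  Ns <- N %/% s

  g <- matrix(0, nch, Ns)
  for (ci in seq_len(nch)) {
    for (j in seq_len(Ns)) {
      acc <- 0
      for (i in ((j - 1) * s + 1):(j * s)) acc <- acc + mat[ci, i]
      g[ci, j] <- acc / s
    }
  }

  vals <- as.numeric(g)
  mu <- sum(vals) / length(vals)
  ss <- 0
  for (v in vals) ss <- ss + (v - mu)^2
  r <- r_coeff * sqrt(ss / length(vals))
  stopifnot(r > 0)

  V <- Ns - (m - 1) * tau
  emb <- matrix(0, V, nch * m)
  for (j in seq_len(V)) {
    k <- 1
    for (ci in seq_len(nch)) {
      for (d in 0:(m - 1)) {
        emb[j, k] <- g[ci, j + d * tau]
        k <- k + 1
      }
    }
  }

  mus <- numeric(V * (V - 1) / 2)
  idx <- 1
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      dmax <- 0
      for (k in seq_len(nch * m)) {
        dk <- abs(emb[i, k] - emb[j, k])
        if (dk > dmax) dmax <- dk
      }
      mus[idx] <- exp(-(dmax / r)^n)
      idx <- idx + 1
    }
  }

  cnt <- rep(0, B)
  for (v in mus) {
    b <- floor(v * B) + 1
    if (b > B) b <- B
    cnt[b] <- cnt[b] + 1
  }
  p <- cnt / sum(cnt)
  h <- 0
  for (t in seq_len(B)) if (p[t] > 0) h <- h - p[t] * log2(p[t])
  h / log2(B)
}

# a small random multichannel signal for property tests
random_signal <- function(seed, n_channels = NULL, n_samples = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_channels)) n_channels <- sample(1:3, 1)
    if (is.null(n_samples)) n_samples <- sample(30:100, 1)
    multichannel_signal(matrix(stats::rnorm(n_channels * n_samples),
                               nrow = n_channels))
  })
}
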