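# Independent brute-force oracles, deliberately implemented with different
# mechanisms than the package internals.

# histogram mutual information via cut()/table(), plain double loop
oracle_mi <- function(x, tau, n_bins = 16) {
  N <- length(x)
  brks <- quantile(x, seq(0, 1, length.out = n_bins + 1))
  brks[1] <- brks[1] - 1
  brks[n_bins + 1] <- brks[n_bins + 1] + 1
  a <- cut(x[1:(N - tau)], brks, labels = FALSE)
  b <- cut(x[(tau + 1):N], brks, labels = FALSE)
  tab <- table(factor(a, 1:n_bins), factor(b, 1:n_bins)) / (N - tau)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in 1:n_bins) {
    for (j in 1:n_bins) {
      if (tab[i, j] > 0)
        s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    }
  }
  as.numeric(s)
}

# O(N^2) sample-entropy pair counts (Chebyshev, self-matches excluded)
oracle_sampen_counts <- function(x, m, r_abs) {
  N <- length(x)
  TT <- N - m
  A <- 0
  B <- 0
  for (i in 1:(TT - 1)) {
    for (j in (i + 1):TT) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r_abs) A <- A + 1
      }
    }
  }
  list(A = A, B = B)
}

# Lempel-Ziv production count by the exhaustive-history definition,
# via substring search on the character representation
oracle_lzc_count <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  cnt <- 0L
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    repeat {
      word_end <- pos + len - 1L
      if (word_end > n) break
      word <- substr(s, pos, word_end)
      hist_ext <- substr(s, 1L, word_end - 1L)
      if (!grepl(word, hist_ext, fixed = TRUE)) break
      len <- len + 1L
    }
    cnt <- cnt + 1L
    pos <- pos + len
  }
  cnt
}

# direct false-nearest-neighbour fraction at one dimension
oracle_fnn_fraction <- function(x, tau, m, rtol = 10, atol = 2) {
  N <- length(x)
  K <- N - m * tau
  sdx <- sd(x)
  E <- sapply(seq_len(m) - 1, function(k) x[seq_len(K) + k * tau])
  E <- matrix(E, nrow = K)
  theiler <- m * tau
  nf <- 0
  np <- 0
  for (i in seq_len(K)) {
    d <- sqrt(rowSums((E - matrix(E[i, ], K, m, byrow = TRUE))^2))
    d[abs(seq_len(K) - i) <= theiler] <- Inf
    d[d == 0] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) next
    Rd <- d[j]
    diff <- abs(x[i + m * tau] - x[j + m * tau])
    np <- np + 1
    if (Rd < 1e-8 * sdx && diff < 1e-8 * sdx) next
    if (diff / Rd > rtol || sqrt(Rd^2 + diff^2) / sdx > atol) nf <- nf + 1
  }
  nf / np
}

excess_kurtosis_free <- function(x) mean((x - mean(x))^4) / sd(x)^4
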