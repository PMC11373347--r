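# Independent brute-force loop implementations of the network statistics,
# used as oracles by several test files.

brute_adjacency <- function(X) {
  nv <- ncol(X)
  A <- matrix(0, nv, nv)
  for (i in seq_len(nv)) for (j in seq_len(nv))
    if (i != j) A[i, j] <- cor(X[, i], X[, j])^2
  A
}

brute_degree <- function(A) {
  nv <- nrow(A)
  k <- numeric(nv)
  for (i in seq_len(nv))
    for (j in seq_len(nv)) if (j != i) k[i] <- k[i] + A[i, j]
  k
}

brute_cc <- function(A) {
  nv <- nrow(A)
  cc <- numeric(nv)
  for (i in seq_len(nv)) {
    num <- 0; ksum <- 0; k2 <- 0
    for (j in seq_len(nv)) {
      if (j == i) next
      ksum <- ksum + A[i, j]; k2 <- k2 + A[i, j]^2
      for (l in seq_len(nv))
        if (l != i && l != j) num <- num + A[i, j] * A[j, l] * A[l, i]
    }
    den <- ksum^2 - k2
    cc[i] <- if (den > 0) num / den else 0
  }
  cc
}

brute_tom <- function(A) {
  nv <- nrow(A)
  k <- brute_degree(A)
  T <- diag(nv)
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(nv)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    T[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  T
}

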