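# Shared fixtures and independent oracles used across the test files.

# Tiny synthetic dataset: fast to train, still exercises every code path.
tinyTruth <- function(seed = 1, pSignal = 0.5, pFp = 0, N = 60, K = 2,
                      I = 6, J = 20) {
  simulateDataset(SimConfig(N = N, K = K, I = I, J = J, pSignal = pSignal,
                            pFp = pFp, seed = seed))
}

tinyConfig <- function(seed = 1, K = 2, maxIters = 40, warmMaxIters = 40) {
  TrainConfig(K = K, maxIters = maxIters, warmMaxIters = warmMaxIters,
              seed = seed)
}

# Brute-force squared-Frobenius residual by explicit double loop.
bruteResidual <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + (A[i, j] - B[i, j])^2
  s
}

# Central finite differences of f at x (a matrix), elementwise.
numGrad <- function(f, M, h = 1e-6) {
  G <- M
  for (i in seq_along(M)) {
    Mp <- M; Mm <- M
    Mp[i] <- M[i] + h
    Mm[i] <- M[i] - h
    G[i] <- (f(Mp) - f(Mm)) / (2 * h)
  }
  G
}

expectGradClose <- function(analytic, numeric, tol = 1e-5, floor = 1e-3) {
  relErr <- max(abs(analytic - numeric) / (floor + abs(numeric)))
  expect_lt(relErr, tol)
}

# Pair-enumeration adjusted Rand index: walks every element pair, counts the
# 2x2 co-assignment table, and applies the Hubert-Arabie pair-count identity.
ariByPairs <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Random non-negative matrix.
rmat <- function(nr, nc, min = 0, max = 1) {
  matrix(stats::runif(nr * nc, min, max), nr, nc)
}
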