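test_that("the interaction gate matches its closed form", {
  # (UV^T) = 0.5 sits exactly at the sigmoid midpoint for any beta
  U <- matrix(1, 1, 1)
  expect_equal(interactionGate(U, matrix(0.5, 1, 1), beta = 7)[1, 1], 0.5)
  # (UV^T) = 1 and 0 at beta = 2: sigma(2) and sigma(-2)
  expect_equal(interactionGate(U, matrix(1, 1, 1), 2)[1, 1],
               0.8807971, tolerance = 1e-6)
  expect_equal(interactionGate(U, matrix(0, 1, 1), 2)[1, 1],
               0.1192029, tolerance = 1e-6)
  expect_equal(interactionGate(U, matrix(0, 1, 1), 2)[1, 1],
               1 - interactionGate(U, matrix(1, 1, 1), 2)[1, 1])
})

test_that("the gate is monotone in every membership entry", {
  set.seed(8)
  for (rep in 1:5) {
    U <- rmat(4, 3); V <- rmat(6, 3)
    S <- interactionGate(U, V, 2)
    i <- sample(4, 1); k <- sample(3, 1)
    U2 <- U; U2[i, k] <- U2[i, k] + runif(1, 0, 2)
    expect_true(all(interactionGate(U2, V, 2) >= S - 1e-12))
    j <- sample(6, 1)
    V2 <- V; V2[j, k] <- V2[j, k] + runif(1, 0, 2)
    expect_true(all(interactionGate(U, V2, 2) >= S - 1e-12))
  }
})

test_that("the regulation model predicts means plus gated linear effects", {
  # all-zero weights: prediction is exactly the baseline mean
  mu <- c(10, 20, 30)
  expect_equal(predictExpression(c(1, 2), matrix(0, 2, 3),
                                 matrix(1, 2, 3), mu), mu)
  # hand example: 1*0.5 + 2*(-1) + 10 = 8.5
  expect_equal(predictExpression(c(1, 2), rbind(0.5, -1),
                                 matrix(1, 2, 1), 10), 8.5)
  # brute-force per-gene summation oracle
  set.seed(9)
  x <- rnorm(5); W <- matrix(rnorm(5 * 7), 5, 7); S <- rmat(5, 7)
  mu2 <- rnorm(7)
  got <- predictExpression(x, W, S, mu2)
  want <- vapply(1:7, function(j) sum(W[, j] * S[, j] * x) + mu2[j], 0)
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(predictExpression(c(1, 2, 3), W, S, mu2), "shape")
})

test_that("the regression cost is zero at exact fits and follows its scaling laws", {
  set.seed(10)
  U <- rmat(3, 2); V <- rmat(8, 2)
  W <- matrix(rnorm(24), 3, 8)
  X <- matrix(rnorm(15, 3), 5, 3)
  S <- interactionGate(U, V, 2)
  mu <- rnorm(8, 10)
  Yexact <- X %*% (W * S) + rep(1, 5) %o% mu
  s2 <- runif(8, 0.5, 2)
  expect_equal(costJW(X, Yexact, U, V, W, s2, mu), 0, tolerance = 1e-18)

  # single-cell hand value: s = 0.5, x = 2, w = 1, mu = 5, y = 5
  # residual = 1, sigma^2 = 2
  U1 <- matrix(1, 1, 1); V1 <- matrix(0.5, 1, 1)
  X1 <- matrix(2, 1, 1); Y1 <- matrix(5, 1, 1); W1 <- matrix(1, 1, 1)
  expect_equal(costJW(X1, Y1, U1, V1, W1, 2, mu = 5,
                      varianceWeighting = "as_written"), 0.25)
  expect_equal(costJW(X1, Y1, U1, V1, W1, 2, mu = 5,
                      varianceWeighting = "chi_square"), 0.5)

  # scaling laws with residuals fixed and every variance doubled: the
  # as_written weight is (sigma^2)^-2, so the cost falls 4-fold; the
  # chi_square weight is (sigma^2)^-1, so it falls 2-fold
  Y <- Yexact + matrix(rnorm(40), 5, 8)
  base_aw <- costJW(X, Y, U, V, W, s2, mu, varianceWeighting = "as_written")
  base_cs <- costJW(X, Y, U, V, W, s2, mu, varianceWeighting = "chi_square")
  expect_equal(costJW(X, Y, U, V, W, 2 * s2, mu,
                      varianceWeighting = "as_written"), base_aw / 4)
  expect_equal(costJW(X, Y, U, V, W, 2 * s2, mu,
                      varianceWeighting = "chi_square"), base_cs / 2)
  expect_error(costJW(X, Y, U, V, W, c(s2[-8], 0), mu), "positive")
})

test_that("regression gradients match central finite differences", {
  set.seed(11)
  for (vw in c("as_written", "chi_square")) {
    U <- rmat(4, 3); V <- rmat(6, 3)
    W <- matrix(rnorm(24), 4, 6)
    X <- matrix(rnorm(5 * 4, 3), 5, 4)
    Y <- matrix(rnorm(5 * 6, 10), 5, 6)
    s2 <- runif(6, 0.5, 2)
    mu <- colMeans(Y)
    g <- gradJW(X, Y, U, V, W, s2, mu, varianceWeighting = vw)
    f <- function(M, slot) {
      if (slot == "W") costJW(X, Y, U, V, M, s2, mu, varianceWeighting = vw)
      else if (slot == "U") costJW(X, Y, M, V, W, s2, mu,
                                   varianceWeighting = vw)
      else costJW(X, Y, U, M, W, s2, mu, varianceWeighting = vw)
    }
    expectGradClose(g$W, numGrad(function(M) f(M, "W"), W))
    expectGradClose(g$U, numGrad(function(M) f(M, "U"), U))
    expectGradClose(g$V, numGrad(function(M) f(M, "V"), V))
  }
})

test_that("a closed gate disconnects a pair from the regression gradient", {
  set.seed(12)
  # large beta drives the gate of non-co-modular pairs to ~0
  U <- rbind(c(1, 0), c(0, 0))   # miRNA 2 belongs to no module
  V <- rbind(c(1, 0), c(0, 1))
  X <- matrix(rnorm(40, 3), 20, 2)
  Y <- matrix(rnorm(40, 10), 20, 2)
  W <- matrix(rnorm(4), 2, 2)
  g <- gradJW(X, Y, U, V, W, c(1, 1), colMeans(Y), beta = 30)
  S <- interactionGate(U, V, 30)
  expect_lt(max(abs(g$W[S < 1e-6])), 1e-4)
  expect_gt(max(abs(g$W[S > 0.5])), 1e-4)
})
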