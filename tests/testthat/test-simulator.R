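test_that("skew-normal draws match the distribution's moments", {
  set.seed(24)
  x <- rskewnorm(2e5, xi = 1, omega = 1, alpha = 5)
  expect_equal(mean(x), skewnormMean(1, 1, 5), tolerance = 0.01)
  delta <- 5 / sqrt(26)
  expect_equal(var(x), 1 - 2 * delta^2 / pi, tolerance = 0.02)
  expect_gt(mean(((x - mean(x)) / sd(x))^3), 0.5)  # strongly right-skewed

  set.seed(25)
  y <- rskewnorm(2e5, xi = 5, omega = 10, alpha = 5)
  expect_equal(mean(y), skewnormMean(5, 10, 5), tolerance = 0.1)
})

test_that("membership sampling respects size contracts and its own transform", {
  set.seed(26)
  M <- sampleMembership(10, 50)
  expect_true(all(M %in% c(0, 1)))
  expect_true(all(colSums(M) >= 2))

  set.seed(27)
  a <- sampleMembership(5, 30)
  set.seed(27)
  b <- sampleMembership(5, 30)
  expect_identical(a, b)

  # distributional oracle: mean generated column size over many matrices
  # against a direct Monte-Carlo of the same size transform
  K <- 10; D <- 200
  set.seed(28)
  colsizes <- unlist(lapply(1:100, function(i)
    colSums(sampleMembership(K, D))))
  set.seed(29)
  m1 <- skewnormMean(1, 1, 5)
  oracle <- pmin(pmax(round((D / K) * rskewnorm(1e4, 1, 1, 5) / m1), 2), D)
  expect_equal(mean(colsizes), mean(oracle), tolerance = 0.05 * mean(oracle))
})

test_that("ground-truth interactions follow shared modules and the sign rate", {
  U <- rbind(c(1, 0), c(0, 1), c(0, 0))
  V <- rbind(c(1, 0), c(1, 1), c(0, 0))
  set.seed(30)
  G <- groundTruthInteractions(U, V, pDown = 0)   # all signs forced to +1
  expect_identical(G != 0, unname(tcrossprod(U, V) >= 1))
  expect_true(all(G %in% c(0, 1)))
  G2 <- groundTruthInteractions(U, V, pDown = 1)  # all signs forced to -1
  expect_true(all(G2[G2 != 0] == -1))
  # an entry with (UV^T) = 3 still clips to magnitude 1
  U3 <- matrix(1, 1, 3); V3 <- matrix(1, 1, 3)
  expect_identical(abs(groundTruthInteractions(U3, V3, 0.5))[1, 1], 1)

  # binomial concentration of the down-regulation fraction
  set.seed(31)
  Ub <- matrix(1, 100, 1); Vb <- matrix(1, 100, 1)  # 10,000 nonzeros
  Gb <- groundTruthInteractions(Ub, Vb, pDown = 0.8)
  frac <- mean(Gb == -1)
  expect_gt(frac, 0.78)
  expect_lt(frac, 0.82)
})

test_that("expression honors the generative means in the no-signal limit", {
  set.seed(32)
  cfg <- SimConfig(N = 400, K = 2, I = 6, J = 30, pSignal = 0, seed = 32)
  G <- matrix(0, 6, 30)
  G[1:2, 1:4] <- 1
  b <- simulateExpression(G, cfg)
  expect_true(all(abs(colMeans(b@X) - 3) < 3 / sqrt(400)))
  expect_true(all(abs(b@mu - 10) < 4 / sqrt(400)))
  # with signal, a regulated gene's mean shifts by pSignal * sum g * E[x]
  cfg2 <- SimConfig(N = 2000, K = 2, I = 6, J = 30, pSignal = 0.5,
                    seed = 33)
  set.seed(33)
  b2 <- simulateExpression(G, cfg2)
  expect_equal(unname(b2@mu[1]), 10 + 0.5 * 2 * 3, tolerance = 0.15)
  expect_equal(unname(b2@mu[30]), 10, tolerance = 0.1)
})

test_that("the putative matrix adds relative false positives over |G|", {
  set.seed(34)
  G <- matrix(0, 40, 100)
  G[sample(4000, 200)] <- sample(c(-1, 1), 200, TRUE, prob = c(0.8, 0.2))

  P0 <- simulatePutative(G, pFp = 0)
  expect_identical(P0, abs(G))  # support preserved, signs erased

  # inclusion-exclusion oracle: E[density] = d + (1 - d) * pFp * d
  d <- mean(G != 0)
  dens <- replicate(40, mean(simulatePutative(G, pFp = 1)))
  expect_equal(mean(dens), d + (1 - d) * d, tolerance = 0.1 * d)

  set.seed(35); A <- simulatePutative(G, 0.7)
  set.seed(35); B <- simulatePutative(G, 0.7)
  expect_identical(A, B)

  # density non-decreasing in pFp at a fixed G
  set.seed(36)
  densities <- vapply(c(0, 0.5, 1, 2), function(pf) {
    set.seed(100)
    mean(simulatePutative(G, pf))
  }, 0)
  expect_true(all(diff(densities) >= 0))
})

test_that("the PPI matrix is the shared-module indicator with empty diagonal", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 0))
  Q <- simulatePPI(V)
  expect_identical(Q, t(Q))
  expect_true(all(diag(Q) == 0))
  # set-intersection oracle
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    shares <- any(V[i, ] == 1 & V[j, ] == 1)
    expect_identical(Q[i, j] == 1, shares)
  }
  # disjoint modules give a block structure with no cross edges
  expect_true(all(Q[1:2, 3:4] == 0))
})

test_that("dataset generation is deterministic per seed and distinct across seeds", {
  t1 <- tinyTruth(seed = 37)
  t2 <- tinyTruth(seed = 37)
  expect_identical(t1@G, t2@G)
  expect_identical(t1@bundle@Y, t2@bundle@Y)
  expect_identical(t1@priors@Q, t2@priors@Q)
  t3 <- tinyTruth(seed = 38)
  expect_false(identical(t1@bundle@X, t3@bundle@X))
  # generator invariant: G nonzero exactly on shared modules
  expect_identical(unname(t1@G != 0),
                   unname(tcrossprod(t1@Utrue, t1@Vtrue) >= 1))
})

test_that("interacting-pair correlation strengthens with the signal", {
  meds <- vapply(c(0.001, 0.05, 0.1, 0.5), function(ps) {
    median(vapply(1:3, function(s) {
      truth <- simulateDataset(SimConfig(N = 300, K = 4, I = 20, J = 100,
                                         pSignal = ps, seed = s))
      pccTopMean(truth@bundle, truth@G)
    }, 0))
  }, 0)
  expect_true(all(diff(meds) > 0))
})
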