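test_that("the total cost composes its four terms and reduces to J_W", {
  set.seed(13)
  truth <- tinyTruth(seed = 13)
  b <- truth@bundle; p <- truth@priors
  U <- rmat(6, 2); V <- rmat(20, 2)
  W <- matrix(rnorm(120, sd = 0.1), 6, 20)
  cfg <- TrainConfig(K = 2)

  # compositional oracle: sum the independently computed parts
  want <- costJW(b@X, b@Y, U, V, W, b@sigma2, b@mu, cfg@beta) +
    cfg@lambda1 * costJU(p@P, U, V) + cfg@lambda2 * costJV(p@Q, V) +
    cfg@lambda3 / 120 * sum(abs(W))
  expect_equal(totalCost(b@X, b@Y, p@P, p@Q, U, V, W, cfg,
                         b@mu, b@sigma2), want, tolerance = 1e-12)

  # lambda = 0 collapses to the regression cost alone
  cfg0 <- TrainConfig(K = 2, lambda1 = 0, lambda2 = 0, lambda3 = 0)
  expect_equal(totalCost(b@X, b@Y, p@P, p@Q, U, V, W, cfg0, b@mu, b@sigma2),
               costJW(b@X, b@Y, U, V, W, b@sigma2, b@mu), tolerance = 1e-12)

  # W = 0: the L1 term contributes nothing whatever lambda3 is
  cfgBig <- TrainConfig(K = 2, lambda3 = 100)
  W0 <- matrix(0, 6, 20)
  expect_equal(totalCost(b@X, b@Y, p@P, p@Q, U, V, W0, cfgBig,
                         b@mu, b@sigma2),
               totalCost(b@X, b@Y, p@P, p@Q, U, V, W0, cfg,
                         b@mu, b@sigma2))
})

test_that("the joint gradient matches finite differences away from w = 0", {
  set.seed(14)
  truth <- tinyTruth(seed = 14, I = 5, J = 8, K = 2, N = 30)
  b <- truth@bundle; p <- truth@priors
  U <- rmat(5, 2); V <- rmat(8, 2)
  # keep weights away from zero so the L1 subgradient is the plain sign
  W <- matrix(sample(c(-1, 1), 40, TRUE) * runif(40, 0.5, 1), 5, 8)
  cfg <- TrainConfig(K = 2)
  g <- totalGrad(b@X, b@Y, p@P, p@Q, U, V, W, cfg, b@mu, b@sigma2)
  f <- function(M, slot) {
    a <- list(U = U, V = V, W = W); a[[slot]] <- M
    totalCost(b@X, b@Y, p@P, p@Q, a$U, a$V, a$W, cfg, b@mu, b@sigma2)
  }
  expectGradClose(g$U, numGrad(function(M) f(M, "U"), U))
  expectGradClose(g$V, numGrad(function(M) f(M, "V"), V))
  expectGradClose(g$W, numGrad(function(M) f(M, "W"), W))
})

test_that("fitting is deterministic given a seed and monotone in cost", {
  truth <- tinyTruth(seed = 15)
  cfg <- tinyConfig(seed = 15)
  f1 <- theiaFit(truth@bundle, truth@priors, cfg)
  f2 <- theiaFit(truth@bundle, truth@priors, cfg)
  expect_identical(f1@U, f2@U)
  expect_identical(f1@V, f2@V)
  expect_identical(f1@W, f2@W)
  expect_identical(f1@trace, f2@trace)
  expect_true(all(diff(f1@trace$total) <= 1e-12))
  expect_true(all(f1@U >= 0) && all(f1@V >= 0))

  f3 <- theiaFit(truth@bundle, truth@priors, tinyConfig(seed = 16))
  expect_false(identical(f1@U, f3@U))
})

test_that("a zero-iteration budget leaves W at zero and predictions at mu", {
  truth <- tinyTruth(seed = 17)
  cfg <- TrainConfig(K = 2, maxIters = 0, warmStart = FALSE, seed = 17)
  fit <- theiaFit(truth@bundle, truth@priors, cfg)
  expect_identical(fit@W, matrix(0, 6, 20))
  expect_identical(nrow(fit@trace), 1L)
  S <- interactionGate(fit@U, fit@V, cfg@beta)
  expect_equal(predictExpression(truth@bundle@X[1, ], fit@W, S,
                                 truth@bundle@mu),
               unname(truth@bundle@mu))
})

test_that("proximal and subgradient L1 modes both shrink and stay monotone", {
  truth <- tinyTruth(seed = 18)
  for (mode in c("subgradient", "proximal")) {
    cfg <- TrainConfig(K = 2, maxIters = 30, warmMaxIters = 20,
                       l1Mode = mode, lambda3 = 5, seed = 18)
    fit <- theiaFit(truth@bundle, truth@priors, cfg)
    expect_true(all(diff(fit@trace$total) <= 1e-12))
  }
})

test_that("warm-starting from the priors never ends above a cold start", {
  finals <- vapply(1:5, function(s) {
    truth <- tinyTruth(seed = s, I = 10, J = 40, K = 3, N = 80)
    warm <- theiaFit(truth@bundle, truth@priors,
                     TrainConfig(K = 3, maxIters = 60, warmMaxIters = 60,
                                 seed = s))
    cold <- theiaFit(truth@bundle, truth@priors,
                     TrainConfig(K = 3, maxIters = 60, warmStart = FALSE,
                                 seed = s))
    c(warm = tail(warm@trace$total, 1), cold = tail(cold@trace$total, 1))
  }, c(warm = 0, cold = 0))
  expect_lte(median(finals["warm", ]), median(finals["cold", ]))
})

test_that("misaligned priors are rejected before training", {
  truth <- tinyTruth(seed = 19)
  pri <- truth@priors
  pri@mirnaIds <- rev(pri@mirnaIds)
  expect_error(theiaFit(truth@bundle, pri, tinyConfig()), "align")
})

test_that("the lambda sweep covers its grid and tolerates weight extremes", {
  truth <- tinyTruth(seed = 60, pSignal = 0.1, pFp = 1, N = 80)
  sw <- sweepLambdas(truth, c(0, 0.5), c(0.5), c(0, 1),
                     config = tinyConfig(seed = 60, maxIters = 20,
                                         warmMaxIters = 20))
  expect_identical(nrow(sw), 4L)
  expect_true(all(is.finite(sw$ari)))
  expect_true(all(is.finite(sw$f1)))
  expect_identical(sort(unique(sw$lambda1)), c(0, 0.5))
})
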