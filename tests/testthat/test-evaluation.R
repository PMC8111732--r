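test_that("comodule ARI is exact on identical structures and chance-corrected", {
  set.seed(40)
  U <- matrix(0, 8, 3); U[cbind(1:8, sample(rep(1:3, c(3, 3, 2))))] <- 1
  V <- matrix(0, 14, 3); V[cbind(1:14, sample(rep(1:3, c(5, 5, 4))))] <- 1
  expect_equal(comoduleARI(U, V, U, V), 1)

  # relabeling the recovered modules leaves the ARI at 1
  perm <- c(3, 1, 2)
  expect_equal(comoduleARI(U, V, U[, perm], V[, perm]), 1)

  # chance correction: random labelings hover around zero
  set.seed(41)
  lab <- membershipLabels(U, 0.5)
  shuffles <- replicate(1000, theia:::.ari(lab, sample(lab)))
  expect_lt(abs(mean(shuffles)), 0.02)
})

test_that("the pair-counting ARI agrees with independent oracles", {
  set.seed(42)
  for (rep in 1:5) {
    a <- sample(0:3, 15, TRUE)
    b <- sample(0:2, 15, TRUE)
    expect_equal(theia:::.ari(a, b), ariByPairs(a, b), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(theia:::.ari(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    # symmetry in the two arguments
    expect_equal(theia:::.ari(a, b), theia:::.ari(b, a))
  }
  # one-module-vs-singletons worked case via the pair oracle
  one <- rep(1, 8)
  pairs <- rep(1:4, each = 2)
  expect_equal(theia:::.ari(one, pairs), ariByPairs(one, pairs))
})

test_that("the co-membership ARI variant detects identical overlap structure", {
  set.seed(43)
  U <- (rmat(8, 3) > 0.6) + 0
  V <- (rmat(10, 3) > 0.6) + 0
  expect_equal(comoduleARI(U, V, U, V, mode = "comembership"), 1)
  # random structure scores well below a perfect match
  U2 <- (rmat(8, 3) > 0.6) + 0
  V2 <- (rmat(10, 3) > 0.6) + 0
  expect_lt(comoduleARI(U, V, U2, V2, mode = "comembership"), 0.8)
})

test_that("direction-aware confusion counts follow the stated convention", {
  G <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("g", 1:3)))
  G["m1", "g1"] <- -1
  G["m2", "g2"] <- 1

  perfect <- data.frame(mirna = c("m1", "m2"), gene = c("g1", "g2"),
                        direction = c("down", "up"))
  expect_equal(interactionF1(G, perfect)@f1, 1)

  none <- data.frame(mirna = character(0), gene = character(0),
                     direction = character(0))
  r0 <- interactionF1(G, none)
  expect_equal(r0@recall, 0)
  expect_equal(r0@f1, 0)

  # hand count: one correct call, one spurious -> P = R = F1 = 0.5
  half <- data.frame(mirna = c("m1", "m3"), gene = c("g1", "g3"),
                     direction = c("down", "down"))
  r <- interactionF1(G, half)
  expect_equal(r@precision, 0.5)
  expect_equal(r@recall, 0.5)
  expect_equal(r@f1, 0.5)

  # a wrong-sign call is a false negative, not a false positive
  flipped <- data.frame(mirna = "m1", gene = "g1", direction = "up")
  rf <- interactionF1(G, flipped)
  expect_identical(unname(rf@counts["fp"]), 0L)
  expect_identical(unname(rf@counts["fn"]), 2L)
  expect_identical(sum(rf@counts), 9L)

  dup <- data.frame(mirna = c("m1", "m1"), gene = c("g1", "g1"),
                    direction = c("down", "down"))
  expect_error(interactionF1(G, dup), "duplicate")
})

test_that("precision-recall integration hits 1 for a perfect scorer", {
  set.seed(44)
  G <- matrix(0, 6, 10)
  G[sample(60, 12)] <- sample(c(-1, 1), 12, TRUE)
  W <- G * runif(60, 0.5, 1.5)              # right signs
  E <- W * 1                                 # |e| separates support exactly
  pr <- precisionRecall(E, W, G)
  expect_equal(pr$aupr, 1)
  expect_true(all(diff(pr$curve$recall[order(pr$curve$threshold)]) <= 0))
})

test_that("an uninformative scorer scores near prevalence", {
  set.seed(45)
  G <- matrix(0, 10, 30)
  G[sample(300, 30)] <- 1                    # prevalence 0.1, all up
  W <- matrix(1, 10, 30)                     # direction always correct
  auprs <- replicate(20, precisionRecall(matrix(runif(300), 10, 30), W,
                                         G)$aupr)
  expect_gt(mean(auprs), 0.06)
  expect_lt(mean(auprs), 0.16)
})

test_that("detection rate is plain set arithmetic over validated pairs", {
  calls <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                      gene = c("g1", "g2", "g3", "g4"))
  val <- data.frame(mirna = c("m1", "m2"), gene = c("g1", "g2"))
  expect_equal(detectionRate(val, calls), 1)
  expect_equal(detectionRate(data.frame(mirna = "mX", gene = "gX"), calls), 0)
  val10 <- data.frame(mirna = sprintf("m%d", 1:10),
                      gene = sprintf("g%d", 1:10))
  expect_equal(detectionRate(val10, calls), 0.4)
  expect_error(detectionRate(character(0), calls), "empty")
})

test_that("the top-correlation statistic matches a null Monte-Carlo oracle", {
  N <- 150; npairs <- 40
  G <- diag(1, npairs, npairs)
  statOf <- function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(N * npairs), N, npairs,
                dimnames = list(NULL, sprintf("m%02d", 1:npairs)))
    Y <- matrix(rnorm(N * npairs, 10), N, npairs,
                dimnames = list(NULL, sprintf("g%02d", 1:npairs)))
    pccTopMean(ExpressionBundle(X, Y), G)
  }
  got <- mean(vapply(1:30, statOf, 0))
  # oracle: same N, same pair count, direct top-10 of |cor| per replicate
  set.seed(46)
  oracle <- mean(replicate(30, {
    cors <- vapply(seq_len(npairs), function(i)
      cor(rnorm(N), rnorm(N)), 0)
    mean(sort(abs(cors), decreasing = TRUE)[1:10])
  }))
  expect_equal(got, oracle, tolerance = 0.15 * oracle)
  expect_error(pccTopMean(tinyTruth(seed = 1)@bundle, matrix(0, 6, 20)),
               "interacting pairs")
})

test_that("Fisher enrichment matches the hypergeometric tail and BH step-up", {
  universe <- sprintf("g%03d", 1:100)
  mod <- universe[1:5]
  sets <- list(hit = universe[1:5], miss = universe[96:100])
  enr <- fisherEnrichment(list(m1 = mod), sets, universe)
  pHit <- enr$pValue[enr$set == "hit"]
  # exhaustive hypergeometric oracle: P(overlap >= 5)
  expect_equal(pHit, dhyper(5, 5, 95, 5) / sum(dhyper(0:5, 5, 95, 5)),
               tolerance = 1e-12)
  expect_equal(pHit, 1 / choose(100, 5), tolerance = 1e-12)
  pMiss <- enr$pValue[enr$set == "miss"]
  expect_equal(pMiss, sum(dhyper(0:5, 5, 95, 5)), tolerance = 1e-12)
  expect_true(all(enr$qValue >= enr$pValue - 1e-15))

  # BH on a hand-checked vector: all q-values collapse to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  # set-size filter drops out-of-range sets before testing
  sets2 <- list(big = universe, ok = universe[1:10])
  enr2 <- fisherEnrichment(list(m1 = mod), sets2, universe,
                           sizeRange = c(5, 50))
  expect_identical(unique(enr2$set), "ok")
  expect_error(fisherEnrichment(list(m1 = mod), sets, character(0)),
               "empty universe")
})

test_that("grid smoothing preserves flat fields and stays in range", {
  M <- matrix(0.7, 5, 8)
  expect_equal(smoothGrid(M, 0.5), M)
  set.seed(47)
  R <- matrix(runif(40), 5, 8)
  S <- smoothGrid(R, 0.5)
  expect_true(all(S >= min(R) - 1e-12 & S <= max(R) + 1e-12))
})

test_that("a tiny sweep runs every cell reproducibly", {
  sc <- SimConfig(N = 40, K = 2, I = 6, J = 20)
  tc <- TrainConfig(K = 2, maxIters = 15, warmMaxIters = 15)
  s1 <- runSweep(c(0, 0.5), c(0, 1), sc, tc, nSeeds = 1)
  s2 <- runSweep(c(0, 0.5), c(0, 1), sc, tc, nSeeds = 1)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 4L)
  expect_true(all(is.finite(s1$ari)))
  expect_true(all(is.finite(s1$f1)))
})
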