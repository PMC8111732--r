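#' Total joint cost
#'
#' \deqn{J = J_W + \lambda_1 J_U + \lambda_2 J_V +
#'   \frac{\lambda_3}{IJ}\sum_{ij}|w_{ij}|.}
#' With \eqn{\lambda_1 = \lambda_2 = \lambda_3 = 0} this reduces exactly to
#' \code{\link{costJW}}.
#'
#' @param X,Y expression matrices (N x I and N x J).
#' @param P,Q binary prior matrices (I x J and J x J).
#' @param U,V,W current factors.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @param mu,sigma2 per-gene means and variances; default to the sample
#'   moments of \code{Y}.
#' @return non-negative scalar.
#' @export
totalCost <- function(X, Y, P, Q, U, V, W, config = TrainConfig(K = ncol(U)),
                      mu = colMeans(Y), sigma2 = apply(Y, 2, stats::var)) {
  jw <- costJW(X, Y, U, V, W, sigma2, mu, config@beta,
               config@varianceWeighting)
  jw + config@lambda1 * costJU(P, U, V) + config@lambda2 * costJV(Q, V) +
    config@lambda3 / (nrow(W) * ncol(W)) * sum(abs(W))
}

# Internal joint cost from precomputed weight vector `a`.
.jointCost <- function(X, Y, P, Q, U, V, W, a, mu, cfg) {
  p <- .jwPieces(X, Y, U, V, W, a, mu, cfg@beta, what = "cost")
  l1 <- sum(abs(W)) / (nrow(W) * ncol(W))
  ju <- costJU(P, U, V)
  jv <- costJV(Q, V)
  list(total = p$cost + cfg@lambda1 * ju + cfg@lambda2 * jv +
         cfg@lambda3 * l1,
       jw = p$cost, ju = ju, jv = jv, l1 = l1)
}

#' Gradient of the total joint cost
#'
#' Analytic gradients with respect to U, V and W.  The L1 term contributes
#' \eqn{\lambda_3/(IJ) \cdot \mathrm{sign}(w_{ij})}, with the subgradient at
#' \eqn{w_{ij} = 0} taken as 0, so a weight leaves zero only once its data
#' gradient exceeds the regularization strength.
#'
#' @inheritParams totalCost
#' @return list with matrices \code{U}, \code{V}, \code{W}.
#' @export
totalGrad <- function(X, Y, P, Q, U, V, W, config = TrainConfig(K = ncol(U)),
                      mu = colMeans(Y), sigma2 = apply(Y, 2, stats::var)) {
  a <- if (config@varianceWeighting == "as_written") sigma2^-2 else sigma2^-1
  jw <- .jwPieces(X, Y, U, V, W, a, mu, config@beta, c("cost", "grad"))
  gu <- gradJU(P, U, V)
  gv <- gradJV(Q, V)
  list(U = jw$dU + config@lambda1 * gu$U,
       V = jw$dV + config@lambda1 * gu$V + config@lambda2 * gv,
       W = jw$dW + config@lambda3 / (nrow(W) * ncol(W)) * sign(W))
}

#' Fit a Theia model
#'
#' Jointly learns the non-negative module membership matrices U (miRNAs) and
#' V (genes) and the signed regulation weight matrix W by minimizing
#' \deqn{J = J_W + \lambda_1 \|P - UV^\top\|^2 + \lambda_2 \|Q - VV^\top\|^2
#'   + \frac{\lambda_3}{IJ}\sum |w_{ij}|}
#' with projected gradient descent.  By default the membership matrices are
#' warm-started: V by a symmetric factorization of the PPI matrix Q, then U
#' by factorizing the putative matrix P with V held fixed; afterwards U, V
#' and W are updated jointly every iteration.  W starts at zero so the
#' initial predictions equal the per-gene means.
#'
#' Steps that would increase the total cost are halved (backtracking), so
#' the accepted-cost trace is monotone non-increasing; each factor is
#' projected onto the non-negative orthant after every step.  The fit is
#' deterministic given \code{config@seed}.
#'
#' @param bundle an \code{\linkS4class{ExpressionBundle}}.
#' @param priors an \code{\linkS4class{InteractionPriors}} aligned to the
#'   bundle's miRNA and gene ids.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @return a \code{\linkS4class{TheiaModel}}.
#' @examples
#' truth <- simulateDataset(SimConfig(N = 60, K = 2, I = 6, J = 20, seed = 7))
#' fit <- theiaFit(truth@bundle, truth@priors,
#'                 TrainConfig(K = 2, maxIters = 30, warmMaxIters = 30))
#' fit
#' @export
theiaFit <- function(bundle, priors, config = TrainConfig()) {
  stopifnot(is(bundle, "ExpressionBundle"), is(priors, "InteractionPriors"))
  validObject(config)
  if (!identical(bundle@mirnaIds, priors@mirnaIds) ||
      !identical(bundle@geneIds, priors@geneIds))
    stop("bundle and priors are not id-aligned; align them before fitting")
  X <- bundle@X; Y <- bundle@Y
  P <- priors@P; Q <- priors@Q
  I <- ncol(X); J <- ncol(Y); K <- config@K
  if (K > min(I, J))
    warning("K = ", K, " exceeds min(I, J) = ", min(I, J))
  mu <- bundle@mu
  sigma2 <- bundle@sigma2
  a <- if (config@varianceWeighting == "as_written") sigma2^-2 else sigma2^-1

  set.seed(config@seed)
  U <- matrix(stats::runif(I * K, 0, 1 / sqrt(K)), I, K)
  V <- matrix(stats::runif(J * K, 0, 1 / sqrt(K)), J, K)

  if (config@warmStart && config@warmMaxIters > 0L) {
    vfit <- pgdFactorize(
      cost = function(f) costJV(Q, f$V),
      grad = function(f) list(V = gradJV(Q, f$V)),
      init = list(V = V),
      maxIters = config@warmMaxIters, tol = config@tol,
      step0 = config@learningRate, window = config@window)
    V <- vfit$factors$V
    ufit <- pgdFactorize(
      cost = function(f) costJU(P, f$U, V),
      grad = function(f) list(U = gradJU(P, f$U, V)$U),
      init = list(U = U),
      maxIters = config@warmMaxIters, tol = config@tol,
      step0 = config@learningRate, window = config@window)
    U <- ufit$factors$U
  }

  W <- matrix(0, I, J)
  l1w <- config@lambda3 / (I * J)
  cur <- .jointCost(X, Y, P, Q, U, V, W, a, mu, config)
  step <- config@learningRate
  n0 <- config@maxIters + 1L
  trace <- data.frame(iteration = integer(n0), total = numeric(n0),
                      jw = numeric(n0), ju = numeric(n0), jv = numeric(n0),
                      l1 = numeric(n0), step = numeric(n0))
  trace[1L, ] <- c(0, cur$total, cur$jw, cur$ju, cur$jv, cur$l1, step)
  it <- 0L
  while (it < config@maxIters) {
    jw <- .jwPieces(X, Y, U, V, W, a, mu, config@beta, c("cost", "grad"))
    gu <- gradJU(P, U, V)
    gv <- gradJV(Q, V)
    gU <- jw$dU + config@lambda1 * gu$U
    gV <- jw$dV + config@lambda1 * gu$V + config@lambda2 * gv
    accepted <- FALSE
    for (h in 1:21) {
      Uc <- projectNonnegative(U - step * gU)
      Vc <- projectNonnegative(V - step * gV)
      if (config@l1Mode == "proximal") {
        Wc <- W - step * jw$dW
        Wc <- sign(Wc) * pmax(abs(Wc) - step * l1w, 0)
      } else {
        Wc <- W - step * (jw$dW + l1w * sign(W))
      }
      cand <- .jointCost(X, Y, P, Q, Uc, Vc, Wc, a, mu, config)
      if (!is.finite(cand$total))
        stop("non-finite total cost at iteration ", it + 1L)
      if (cand$total <= cur$total) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    U <- Uc; V <- Vc; W <- Wc
    cur <- cand
    it <- it + 1L
    trace[it + 1L, ] <- c(it, cur$total, cur$jw, cur$ju, cur$jv, cur$l1,
                          step)
    step <- min(step * 2, 1e3 * config@learningRate)
    if (it >= config@window) {
      old <- trace$total[it + 1L - config@window]
      if ((old - cur$total) < config@tol * max(old, .Machine$double.eps))
        break
    }
  }
  new("TheiaModel", U = U, V = V, W = W,
      mirnaIds = bundle@mirnaIds, geneIds = bundle@geneIds,
      config = config, trace = trace[seq_len(it + 1L), , drop = FALSE])
}

#' Sweep the cost-weight grid on one synthetic dataset
#'
#' Reproduces the exhaustive search that fixed the default weights: fits
#' the model for every (lambda1, lambda2, lambda3) combination on a single
#' synthetic dataset and records comodule ARI and direction-aware F1.
#' The published search held the generator at pSignal = 0.1, pFp = 1.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}} to fit against.
#' @param lambda1Grid,lambda2Grid,lambda3Grid numeric axes (defaults: 0 to
#'   1 by 0.25).
#' @param config template \code{\linkS4class{TrainConfig}}; its lambdas are
#'   overridden per cell.
#' @param TU,TV evaluation membership cutoffs.
#' @param verbose print one line per cell.
#' @return data.frame with columns lambda1, lambda2, lambda3, ari, f1.
#' @export
sweepLambdas <- function(truth,
                         lambda1Grid = seq(0, 1, by = 0.25),
                         lambda2Grid = seq(0, 1, by = 0.25),
                         lambda3Grid = seq(0, 1, by = 0.25),
                         config = TrainConfig(), TU = 0.5, TV = 0.5,
                         verbose = FALSE) {
  stopifnot(is(truth, "SyntheticTruth"))
  grid <- expand.grid(lambda1 = lambda1Grid, lambda2 = lambda2Grid,
                      lambda3 = lambda3Grid)
  res <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    cfg@lambda1 <- grid$lambda1[r]
    cfg@lambda2 <- grid$lambda2[r]
    cfg@lambda3 <- grid$lambda3[r]
    fit <- theiaFit(truth@bundle, truth@priors, cfg)
    ev <- evaluateModel(fit, truth, TU = TU, TV = TV)
    if (verbose)
      message(sprintf("lambda=(%g, %g, %g) ari=%.3f f1=%.3f",
                      cfg@lambda1, cfg@lambda2, cfg@lambda3, ev@ari, ev@f1))
    res[[r]] <- c(ari = ev@ari, f1 = ev@f1)
  }
  cbind(grid, do.call(rbind, res))
}
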