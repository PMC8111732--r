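#' Project a matrix onto the non-negative orthant
#'
#' Elementwise \code{max(M, 0)}; the projection step of projected gradient
#' descent for NMF.  Idempotent.
#'
#' @param M numeric matrix.
#' @return non-negative matrix of the same shape.
#' @export
projectNonnegative <- function(M) {
  M[M < 0] <- 0
  M
}

#' Symmetric factorization cost of the PPI matrix
#'
#' Squared Frobenius norm \eqn{\|Q - VV^\top\|_F^2}.  The norm is squared so
#' the objective is smooth; the un-squared norm only rescales gradients.
#'
#' @param Q binary symmetric matrix J x J.
#' @param V non-negative matrix J x K.
#' @return non-negative scalar; zero iff \eqn{VV^\top = Q} exactly.
#' @export
costJV <- function(Q, V) {
  if (nrow(Q) != ncol(Q) || nrow(V) != nrow(Q))
    stop("shape mismatch: Q must be J x J and V must be J x K")
  R <- Q - tcrossprod(V)
  sum(R * R)
}

#' Putative-matrix factorization cost
#'
#' Squared Frobenius norm \eqn{\|P - UV^\top\|_F^2}.
#'
#' @param P binary matrix I x J.
#' @param U non-negative matrix I x K.
#' @param V non-negative matrix J x K.
#' @return non-negative scalar.
#' @export
costJU <- function(P, U, V) {
  if (nrow(P) != nrow(U) || ncol(P) != nrow(V) || ncol(U) != ncol(V))
    stop("shape mismatch: P must be I x J with U I x K and V J x K")
  R <- P - tcrossprod(U, V)
  sum(R * R)
}

#' Gradient of the symmetric factorization cost
#'
#' Full derivative of \eqn{\|Q - VV^\top\|_F^2} accounting for both
#' appearances of V: \eqn{-2(Q - VV^\top)V - 2(Q - VV^\top)^\top V}.
#'
#' @inheritParams costJV
#' @return J x K gradient matrix.
#' @export
gradJV <- function(Q, V) {
  if (nrow(Q) != ncol(Q) || nrow(V) != nrow(Q))
    stop("shape mismatch: Q must be J x J and V must be J x K")
  R <- Q - tcrossprod(V)
  -2 * (R %*% V) - 2 * crossprod(R, V)
}

#' Gradients of the putative factorization cost
#'
#' @inheritParams costJU
#' @return list with components \code{U} (I x K) and \code{V} (J x K).
#' @export
gradJU <- function(P, U, V) {
  if (nrow(P) != nrow(U) || ncol(P) != nrow(V) || ncol(U) != ncol(V))
    stop("shape mismatch: P must be I x J with U I x K and V J x K")
  R <- P - tcrossprod(U, V)
  list(U = -2 * (R %*% V), V = -2 * crossprod(R, U))
}

#' Projected gradient descent over non-negative factors
#'
#' Generic minimizer used for the warm-start factorizations and exposed for
#' standalone NMF.  \code{cost} and \code{grad} take a named list of factor
#' matrices; each accepted step projects every factor onto the non-negative
#' orthant.  The step size is adapted by backtracking: a step that would
#' increase the cost is halved (up to \code{maxHalvings} times); an accepted
#' step lets the size grow again, so the recorded cost trace is monotone
#' non-increasing regardless of the initial rate.
#'
#' Convergence is declared when the relative cost decrease over a window of
#' \code{window} accepted iterations drops below \code{tol}.
#'
#' @param cost function(factors) -> scalar.
#' @param grad function(factors) -> named list of gradient matrices.
#' @param init named list of non-negative starting matrices.
#' @param maxIters maximum accepted iterations; 0 returns \code{init}.
#' @param tol relative cost-change convergence tolerance.
#' @param step0 initial step size.
#' @param window iterations over which the relative change is measured.
#' @param maxHalvings backtracking budget per iteration.
#' @return list with \code{factors}, final \code{cost}, \code{iterations},
#'   final \code{step}, and the accepted \code{trace} of costs.
#' @export
pgdFactorize <- function(cost, grad, init, maxIters = 200, tol = 1e-5,
                         step0 = 1e-2, window = 10, maxHalvings = 30) {
  factors <- lapply(init, projectNonnegative)
  f <- cost(factors)
  if (!is.finite(f)) stop("non-finite cost at initialization")
  trace <- numeric(maxIters + 1L)
  trace[1L] <- f
  step <- step0
  it <- 0L
  while (it < maxIters) {
    g <- grad(factors)
    accepted <- FALSE
    for (h in seq_len(maxHalvings + 1L)) {
      cand <- mapply(function(Fm, Gm) projectNonnegative(Fm - step * Gm),
                     factors, g[names(factors)], SIMPLIFY = FALSE)
      fc <- cost(cand)
      if (!is.finite(fc))
        stop("non-finite cost at iteration ", it + 1L)
      if (fc <= f) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    factors <- cand
    f <- fc
    it <- it + 1L
    trace[it + 1L] <- f
    step <- min(step * 2, 1e3 * step0)
    w <- min(window, it)
    old <- trace[it + 1L - w]
    if (w >= window && (old - f) < tol * max(old, .Machine$double.eps))
      break
  }
  list(factors = factors, cost = f, iterations = it, step = step,
       trace = trace[seq_len(it + 1L)])
}
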