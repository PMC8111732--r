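#' Sigmoid interaction gate
#'
#' Computes the soft interaction indicator
#' \deqn{s_{ij} = \sigma(\beta(2 (UV^\top)_{ij} - 1)),}
#' where \eqn{\sigma} is the logistic sigmoid.  The gate is a continuous
#' probability in (0, 1): it approaches 1 as miRNA i and gene j share more
#' (or stronger) module memberships, crosses 0.5 exactly when
#' \eqn{(UV^\top)_{ij} = 0.5}, and falls to \eqn{\sigma(-\beta)} for pairs
#' with no shared module.  Multiplying the regulation weights by the gate
#' disconnects non-co-modular pairs from the regression.
#'
#' @param U non-negative matrix I x K.
#' @param V non-negative matrix J x K.
#' @param beta positive sigmoid scale (default 2).
#' @return matrix I x J with entries strictly in (0, 1).
#' @examples
#' U <- matrix(1, 1, 1); V <- matrix(0.5, 1, 1)
#' interactionGate(U, V, beta = 2)  # exactly 0.5
#' @export
interactionGate <- function(U, V, beta = 2) {
  if (ncol(U) != ncol(V)) stop("U and V must share the module dimension K")
  stopifnot(beta > 0)
  A <- tcrossprod(U, V)
  1 / (1 + exp(-(beta * (2 * A - 1))))
}

#' Predict gene expression for one sample
#'
#' The gated linear regulation model
#' \deqn{\hat y_{nj} = \sum_i w_{ij} s_{ij} x_{ni} + \mu_j.}
#' Pairs whose gate is zero contribute nothing, whatever their weight.
#'
#' @param x numeric vector of length I, one sample of miRNA expression.
#' @param W regulation weight matrix I x J.
#' @param S gate matrix I x J.
#' @param mu numeric vector of length J of per-gene baseline means.
#' @return numeric vector of length J.
#' @export
predictExpression <- function(x, W, S, mu) {
  if (length(x) != nrow(W) || !identical(dim(W), dim(S)) ||
      length(mu) != ncol(W))
    stop("shape mismatch in predictExpression")
  drop(x %*% (W * S)) + mu
}

#' Variance-scaled regression cost of the W-net
#'
#' \deqn{J_W = \frac{1}{N}\sum_n \| (\hat y_n - y_n) \bullet \sigma^{-2} \|^2}
#' with \eqn{\hat y_n} from the gated linear model.  Under the default
#' \code{"as_written"} weighting the residual is multiplied by
#' \eqn{\sigma_j^{-2}} before the squared norm, so each gene's squared
#' residual carries a \eqn{\sigma_j^{-4}} weight; \code{"chi_square"}
#' instead weights the squared residual by \eqn{\sigma_j^{-2}}.  With unit
#' gene variances the two coincide.
#'
#' @param X miRNA expression N x I.
#' @param Y gene expression N x J.
#' @param U,V non-negative membership matrices.
#' @param W regulation weight matrix I x J.
#' @param sigma2 per-gene variances, strictly positive.
#' @param mu per-gene baseline means; defaults to the column means of Y.
#' @param beta sigmoid scale of the gate.
#' @param varianceWeighting \code{"as_written"} or \code{"chi_square"}.
#' @return non-negative scalar; zero iff predictions match Y exactly.
#' @export
costJW <- function(X, Y, U, V, W, sigma2, mu = colMeans(Y), beta = 2,
                   varianceWeighting = c("as_written", "chi_square")) {
  varianceWeighting <- match.arg(varianceWeighting)
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  S <- interactionGate(U, V, beta)
  R <- X %*% (W * S) + rep(1, nrow(X)) %o% mu - Y
  a <- if (varianceWeighting == "as_written") sigma2^-2 else sigma2^-1
  sum(sweep(R * R, 2, a, `*`)) / nrow(X)
}

# Internal: cost and gradients of J_W given precomputed pieces.
# Returns list(cost, dW, dU, dV). `a` is the per-gene residual weight
# (sigma^-4 for as_written, sigma^-2 for chi_square).
.jwPieces <- function(X, Y, U, V, W, a, mu, beta, what = c("cost", "grad")) {
  S <- interactionGate(U, V, beta)
  WS <- W * S
  R <- X %*% WS + rep(1, nrow(X)) %o% mu - Y
  Rw <- sweep(R, 2, a, `*`)
  out <- list(cost = sum(R * Rw) / nrow(X))
  if ("grad" %in% what) {
    XtG <- crossprod(X, Rw) * (2 / nrow(X))   # d JW / d (W o S)
    out$dW <- XtG * S
    M <- XtG * W * S * (1 - S) * (2 * beta)   # d JW / d (UV^T)
    out$dU <- M %*% V
    out$dV <- crossprod(M, U)
  }
  out
}

#' Gradient of the regression cost
#'
#' Analytic gradients of \code{\link{costJW}} with respect to W, U and V,
#' propagating through the sigmoid gate.
#'
#' @inheritParams costJW
#' @return list with matrices \code{W} (I x J), \code{U} (I x K),
#'   \code{V} (J x K).
#' @export
gradJW <- function(X, Y, U, V, W, sigma2, mu = colMeans(Y), beta = 2,
                   varianceWeighting = c("as_written", "chi_square")) {
  varianceWeighting <- match.arg(varianceWeighting)
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  a <- if (varianceWeighting == "as_written") sigma2^-2 else sigma2^-1
  p <- .jwPieces(X, Y, U, V, W, a, mu, beta, what = c("cost", "grad"))
  list(W = p$dW, U = p$dU, V = p$dV)
}
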