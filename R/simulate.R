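#' Draw from a skew-normal distribution
#'
#' Samples SN(xi, omega, alpha) via the standard convolution
#' representation: with \eqn{\delta = \alpha/\sqrt{1+\alpha^2}} and
#' independent standard normals \eqn{z_0, z_1}, the variate
#' \eqn{\xi + \omega(\delta |z_0| + \sqrt{1-\delta^2}\, z_1)} is
#' skew-normal.  Positive \code{alpha} gives the right-skewed shapes used
#' for module sizes and per-element module counts.
#'
#' @param n number of draws.
#' @param xi location parameter.
#' @param omega positive scale parameter.
#' @param alpha shape (skewness) parameter.
#' @return numeric vector of length \code{n}.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  xi + omega * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' Mean of a skew-normal distribution
#'
#' \eqn{E[SN(\xi,\omega,\alpha)] = \xi + \omega\delta\sqrt{2/\pi}} with
#' \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}.
#'
#' @param xi,omega,alpha skew-normal parameters.
#' @return scalar mean.
#' @export
skewnormMean <- function(xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

#' Sample a binary membership matrix
#'
#' Generates a D x K binary matrix.  Module sizes (column sums) follow the
#' positively skewed SN(1, 1, 5) shape, normalized by its mean and scaled
#' by the natural module size D/K, then rounded and clipped to [2, D]: the
#' K modules tile the element pool on average while a few modules are much
#' larger than the rest.  The number of modules per row follows its own
#' skew-normal with location D/K; the rounded, clipped ([0, K]) draws act
#' as selection weights: each column is filled by weighted sampling of rows
#' without replacement, so high-degree rows (hubs) join more modules,
#' coupling the two marginals configuration-model style.
#'
#' @param K number of modules (>= 1).
#' @param D number of elements (>= 2).
#' @param sizeParams numeric c(xi, omega, alpha) of the module-size
#'   skew-normal shape (default c(1, 1, 5)).
#' @param degreeParams numeric c(xi, omega, alpha) of the per-row degree
#'   skew-normal (default location D/K, scale 10, shape 5).
#' @param sizeScale multiplier applied to the mean-normalized size draw;
#'   defaults to D/K so that mean module size is about D/K.
#' @return binary matrix D x K with every column sum >= 2.
#' @export
sampleMembership <- function(K, D, sizeParams = c(1, 1, 5),
                             degreeParams = c(D / K, 10, 5),
                             sizeScale = D / K) {
  stopifnot(K >= 1, D >= 2)
  m1 <- skewnormMean(sizeParams[1], sizeParams[2], sizeParams[3])
  raw <- rskewnorm(K, sizeParams[1], sizeParams[2], sizeParams[3])
  sizes <- pmin(pmax(round(sizeScale * raw / m1), 2L), D)
  degrees <- pmin(pmax(round(rskewnorm(D, degreeParams[1], degreeParams[2],
                                       degreeParams[3])), 0L), K)
  wts <- degrees + 1e-9  # keep zero-degree rows selectable at negligible rate
  M <- matrix(0, D, K)
  for (k in seq_len(K)) {
    rows <- sample.int(D, sizes[k], prob = wts)
    M[rows, k] <- 1
  }
  M
}

#' Signed ground-truth interaction matrix
#'
#' \deqn{g_{ij} = \min((U V^\top)_{ij}, 1)\,(2 b_{ij} - 1)} with
#' \eqn{\Pr(b_{ij} = 0) = p_{\mathrm{down}}}: interactions exist exactly
#' between pairs sharing at least one module, and a fraction
#' \eqn{p_{\mathrm{down}}} of them are down-regulating (-1).
#'
#' @param Utrue,Vtrue binary membership matrices (I x K, J x K).
#' @param pDown probability of a -1 sign among nonzeros.
#' @return matrix in \{-1, 0, 1\}^(I x J).
#' @export
groundTruthInteractions <- function(Utrue, Vtrue, pDown = 0.8) {
  stopifnot(all(Utrue %in% c(0, 1)), all(Vtrue %in% c(0, 1)))
  A <- pmin(tcrossprod(Utrue, Vtrue), 1)
  B <- matrix(stats::rbinom(length(A), 1, 1 - pDown), nrow(A), ncol(A))
  A * (2 * B - 1)
}

#' Simulate expression from a ground-truth interaction matrix
#'
#' MiRNA expression is i.i.d. Gaussian,
#' \eqn{x_{ni} \sim N(\mu_x, \sigma_x^2)}; gene expression responds
#' linearly to its regulators,
#' \eqn{y_{nj} \sim N(\mu_y + p_{\mathrm{signal}} \sum_i g_{ij} x_{ni},
#' \sigma_y^2)}.
#'
#' @param G signed interaction matrix I x J.
#' @param config a \code{\linkS4class{SimConfig}} (dimensions must match G).
#' @return an \code{\linkS4class{ExpressionBundle}}.
#' @export
simulateExpression <- function(G, config) {
  N <- config@N; I <- nrow(G); J <- ncol(G)
  X <- matrix(stats::rnorm(N * I, config@muX, sqrt(config@sigmaX2)), N, I)
  M <- config@muY + config@pSignal * (X %*% G)
  Y <- M + matrix(stats::rnorm(N * J, 0, sqrt(config@sigmaY2)), N, J)
  dimnames(X) <- list(sprintf("sample%04d", seq_len(N)),
                      sprintf("mir%03d", seq_len(I)))
  dimnames(Y) <- list(rownames(X), sprintf("gene%04d", seq_len(J)))
  ExpressionBundle(X, Y)
}

#' Simulate the putative interaction matrix
#'
#' \eqn{p_{ij} = \max(|g_{ij}|, b'_{ij})} with
#' \eqn{\Pr(b'_{ij} = 1) = p_{\mathrm{fp}} \cdot d} where \eqn{d} is the
#' density of nonzeros in G.  The magnitude of g is used so that
#' down-regulating true interactions (g = -1) stay in the putative support;
#' the relative rate makes the expected density of P roughly
#' \eqn{(1 + p_{\mathrm{fp}})\, d} (minus overlap), independent of the
#' dimensions of G.
#'
#' @param G signed interaction matrix.
#' @param pFp relative false-positive rate (>= 0).
#' @return binary matrix with the shape of G.
#' @export
simulatePutative <- function(G, pFp = 0) {
  stopifnot(pFp >= 0)
  d <- mean(G != 0)
  prob <- min(1, pFp * d)
  B <- matrix(stats::rbinom(length(G), 1, prob), nrow(G), ncol(G))
  pmax(abs(G), B)
}

#' Simulate the protein-protein interaction matrix
#'
#' \eqn{q_{jj'} = \min((V V^\top)_{jj'}, 1)}: genes are connected iff they
#' share at least one module.  The diagonal is zeroed (self-interaction
#' carries no information for a PPI prior).
#'
#' @param Vtrue binary gene membership matrix J x K.
#' @return binary symmetric matrix J x J with zero diagonal.
#' @export
simulatePPI <- function(Vtrue) {
  stopifnot(all(Vtrue %in% c(0, 1)))
  Q <- pmin(tcrossprod(Vtrue), 1)
  diag(Q) <- 0
  Q
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Draws binary module memberships (skew-normal sizes and degrees), the
#' signed true interaction matrix, Gaussian expression with linear miRNA
#' effects, the putative interaction matrix with controllable false-positive
#' rate, and the PPI matrix.  Fully deterministic given \code{config@seed}.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return a \code{\linkS4class{SyntheticTruth}}.
#' @examples
#' truth <- simulateDataset(SimConfig(N = 50, K = 3, I = 10, J = 40,
#'                                    seed = 1))
#' truth
#' @export
simulateDataset <- function(config = SimConfig()) {
  validObject(config)
  set.seed(config@seed)
  Utrue <- sampleMembership(config@K, config@I,
                            c(config@sizeXi, config@sizeOmega,
                              config@sizeAlpha),
                            c(config@I / config@K, config@degreeOmega,
                              config@degreeAlpha))
  Vtrue <- sampleMembership(config@K, config@J,
                            c(config@sizeXi, config@sizeOmega,
                              config@sizeAlpha),
                            c(config@J / config@K, config@degreeOmega,
                              config@degreeAlpha))
  G <- groundTruthInteractions(Utrue, Vtrue, config@pDown)
  bundle <- simulateExpression(G, config)
  P <- simulatePutative(G, config@pFp)
  Q <- simulatePPI(Vtrue)
  dimnames(P) <- list(bundle@mirnaIds, bundle@geneIds)
  dimnames(Q) <- list(bundle@geneIds, bundle@geneIds)
  priors <- InteractionPriors(P, Q)
  dimnames(G) <- dimnames(P)
  new("SyntheticTruth", Utrue = Utrue, Vtrue = Vtrue, G = unname(G) + 0,
      bundle = bundle, priors = priors, config = config)
}
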