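#' @import methods
NULL

#' Paired miRNA and gene expression matrices
#'
#' An \code{ExpressionBundle} holds the miRNA expression matrix \code{X}
#' (N samples by I miRNAs) and the gene expression matrix \code{Y}
#' (N samples by J genes), together with the identifiers of the samples and
#' features and the per-gene sample mean \eqn{\mu_j} and sample variance
#' \eqn{\sigma_j^2} that the regression network of Theia conditions on.
#'
#' Both matrices are oriented samples-by-features.  Genes whose sample
#' variance is numerically zero are rejected by the constructor (the
#' regression cost divides by \eqn{\sigma_j^2}).
#'
#' @slot X numeric matrix, N x I miRNA expression.
#' @slot Y numeric matrix, N x J gene expression.
#' @slot sampleIds character vector of length N.
#' @slot mirnaIds character vector of length I.
#' @slot geneIds character vector of length J.
#' @slot mu numeric vector of length J, per-gene sample mean of \code{Y}.
#' @slot sigma2 numeric vector of length J, per-gene sample variance of
#'   \code{Y}; strictly positive.
#'
#' @seealso \code{\link{ExpressionBundle}} for the validating constructor.
#' @export
setClass("ExpressionBundle",
  representation(
    X = "matrix",
    Y = "matrix",
    sampleIds = "character",
    mirnaIds = "character",
    geneIds = "character",
    mu = "numeric",
    sigma2 = "numeric"
  )
)

setValidity("ExpressionBundle", function(object) {
  msg <- character(0)
  N <- nrow(object@X)
  if (N < 2L) msg <- c(msg, "need at least 2 samples")
  if (nrow(object@Y) != N)
    msg <- c(msg, "X and Y must have the same number of rows (samples)")
  if (length(object@sampleIds) != N)
    msg <- c(msg, "sampleIds length must equal nrow(X)")
  if (length(object@mirnaIds) != ncol(object@X))
    msg <- c(msg, "mirnaIds length must equal ncol(X)")
  if (length(object@geneIds) != ncol(object@Y))
    msg <- c(msg, "geneIds length must equal ncol(Y)")
  if (length(object@mu) != ncol(object@Y) ||
      length(object@sigma2) != ncol(object@Y))
    msg <- c(msg, "mu and sigma2 must have one entry per gene")
  if (length(object@sigma2) && any(object@sigma2 <= 0))
    msg <- c(msg, "sigma2 must be strictly positive for every gene")
  if (ncol(object@Y) > 0 && nrow(object@Y) > 1) {
    cm <- colMeans(object@Y)
    if (max(abs(cm - object@mu)) > 1e-6 * (1 + max(abs(cm))))
      msg <- c(msg, "mu does not match the column means of Y")
  }
  if (anyDuplicated(object@mirnaIds)) msg <- c(msg, "duplicate miRNA ids")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionBundle
#'
#' Builds the paired expression container from two samples-by-features
#' matrices, computing the per-gene sample mean and variance.  Genes with
#' sample variance below \code{varTol} are dropped with a warning, since the
#' regression cost weights residuals by the inverse variance.  An optional
#' minimum-mean-expression filter (off by default) mirrors the common
#' preprocessing step of discarding features with very small expression
#' values; it uses the feature mean as the criterion.
#'
#' @param X numeric matrix N x I of miRNA expression with column names
#'   (miRNA ids); row names are sample ids.
#' @param Y numeric matrix N x J of gene expression with column names
#'   (gene ids); row names must match those of \code{X}.
#' @param minMeanExpr optional numeric; when non-\code{NULL}, miRNAs and
#'   genes whose mean expression is below this value are dropped.
#' @param varTol genes with sample variance below this tolerance are dropped.
#' @return an \code{\linkS4class{ExpressionBundle}}.
#' @examples
#' X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("m1", "m2")))
#' Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' eb <- ExpressionBundle(X, Y)
#' geneMeans(eb)
#' @export
ExpressionBundle <- function(X, Y, minMeanExpr = NULL, varTol = 1e-12) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y))
    stop("X and Y must be numeric matrices")
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (samples)")
  if (is.null(colnames(X)) || is.null(colnames(Y)))
    stop("X and Y need column names (miRNA / gene ids)")
  sampleIds <- rownames(X)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample%04d", seq_len(nrow(X)))
  if (!is.null(rownames(Y)) && !identical(rownames(Y), sampleIds))
    stop("sample ids of X and Y disagree")
  if (!is.null(minMeanExpr)) {
    keepX <- colMeans(X) >= minMeanExpr
    keepY <- colMeans(Y) >= minMeanExpr
    if (!all(keepX) || !all(keepY))
      message(sum(!keepX), " miRNAs and ", sum(!keepY),
              " genes below mean expression ", minMeanExpr, " dropped")
    X <- X[, keepX, drop = FALSE]
    Y <- Y[, keepY, drop = FALSE]
  }
  v <- apply(Y, 2, stats::var)
  low <- v < varTol
  if (any(low)) {
    warning(sum(low), " gene(s) with near-zero sample variance dropped: ",
            paste(utils::head(colnames(Y)[low], 5), collapse = ", "))
    Y <- Y[, !low, drop = FALSE]
    v <- v[!low]
  }
  new("ExpressionBundle",
      X = unname(X) + 0, Y = unname(Y) + 0,
      sampleIds = trimws(sampleIds),
      mirnaIds = trimws(colnames(X)),
      geneIds = trimws(colnames(Y)),
      mu = unname(colMeans(Y)),
      sigma2 = unname(v))
}

#' Binary interaction priors
#'
#' Holds the putative miRNA-gene interaction matrix \code{P} (I x J, e.g.
#' built from sequence-based target predictions) and the symmetric
#' protein-protein interaction matrix \code{Q} (J x J).  Both are strictly
#' binary; the diagonal of \code{Q} is forced to zero on construction.
#'
#' @slot P binary matrix I x J.
#' @slot Q binary symmetric matrix J x J with zero diagonal.
#' @slot mirnaIds character, row ids of \code{P}.
#' @slot geneIds character, column ids of \code{P} and row/column ids of
#'   \code{Q}.
#' @export
setClass("InteractionPriors",
  representation(
    P = "matrix",
    Q = "matrix",
    mirnaIds = "character",
    geneIds = "character"
  )
)

setValidity("InteractionPriors", function(object) {
  msg <- character(0)
  if (!all(object@P %in% c(0, 1))) msg <- c(msg, "P must be binary")
  if (!all(object@Q %in% c(0, 1))) msg <- c(msg, "Q must be binary")
  if (nrow(object@Q) != ncol(object@Q) || !isTRUE(all.equal(object@Q, t(object@Q))))
    msg <- c(msg, "Q must be symmetric")
  if (nrow(object@Q) > 0 && any(diag(object@Q) != 0))
    msg <- c(msg, "Q diagonal must be zero")
  if (ncol(object@P) != nrow(object@Q))
    msg <- c(msg, "ncol(P) must equal nrow(Q)")
  if (length(object@mirnaIds) != nrow(object@P))
    msg <- c(msg, "mirnaIds length must equal nrow(P)")
  if (length(object@geneIds) != ncol(object@P))
    msg <- c(msg, "geneIds length must equal ncol(P)")
  if (length(msg)) msg else TRUE
})

#' Construct InteractionPriors
#'
#' @param P binary matrix I x J with dimnames, or unnamed when
#'   \code{mirnaIds}/\code{geneIds} are given.
#' @param Q binary matrix J x J; symmetrized with \code{pmax(Q, t(Q))} and
#'   diagonal zeroed.
#' @param mirnaIds,geneIds optional ids overriding the dimnames.
#' @return an \code{\linkS4class{InteractionPriors}}.
#' @export
InteractionPriors <- function(P, Q, mirnaIds = rownames(P),
                              geneIds = colnames(P)) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  if (is.null(mirnaIds) || is.null(geneIds))
    stop("P needs row and column ids")
  Q <- pmax(Q, t(Q))
  diag(Q) <- 0
  new("InteractionPriors",
      P = unname(P) + 0, Q = unname(Q) + 0,
      mirnaIds = trimws(mirnaIds), geneIds = trimws(geneIds))
}

#' Training configuration for the joint optimizer
#'
#' Captures every tunable of the joint cost
#' \deqn{J = J_W + \lambda_1 J_U + \lambda_2 J_V +
#'   \frac{\lambda_3}{IJ} \sum_{ij} |w_{ij}|}
#' and of the projected-gradient loop minimizing it.
#'
#' @slot K number of modules.
#' @slot lambda1,lambda2,lambda3 non-negative weights of the putative-matrix
#'   factorization, PPI factorization and L1 terms (defaults 0.5, 0.5, 0.25).
#' @slot beta positive sigmoid scale of the interaction gate (default 2).
#' @slot TU,TV membership cutoffs used when extracting comodules
#'   (defaults 0.5 and 0.25).
#' @slot TW edge-calling threshold on \eqn{|e_{ij}|} (default 0.001).
#' @slot learningRate initial projected-gradient step size.
#' @slot maxIters maximum joint iterations.
#' @slot warmStart logical; factorize Q (then P) before joint descent.
#' @slot warmMaxIters maximum iterations of each warm-start factorization.
#' @slot tol relative total-cost change declaring convergence.
#' @slot window iterations over which the relative change is measured.
#' @slot varianceWeighting \code{"as_written"} multiplies the residual by
#'   \eqn{\sigma_j^{-2}} before the squared norm; \code{"chi_square"} weights
#'   the squared residual by \eqn{\sigma_j^{-2}}.
#' @slot l1Mode \code{"subgradient"} (subgradient 0 at w = 0) or
#'   \code{"proximal"} (soft-thresholding update of W).
#' @slot seed integer RNG seed; fixes initialization and therefore the fit.
#' @export
setClass("TrainConfig",
  representation(
    K = "integer",
    lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
    beta = "numeric",
    TU = "numeric", TV = "numeric", TW = "numeric",
    learningRate = "numeric",
    maxIters = "integer",
    warmStart = "logical",
    warmMaxIters = "integer",
    tol = "numeric",
    window = "integer",
    varianceWeighting = "character",
    l1Mode = "character",
    seed = "integer"
  ),
  prototype(
    K = 10L, lambda1 = 0.5, lambda2 = 0.5, lambda3 = 0.25, beta = 2,
    TU = 0.5, TV = 0.25, TW = 0.001,
    learningRate = 1e-2, maxIters = 250L,
    warmStart = TRUE, warmMaxIters = 200L,
    tol = 1e-5, window = 10L,
    varianceWeighting = "as_written", l1Mode = "subgradient", seed = 1L
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (any(c(object@lambda1, object@lambda2, object@lambda3) < 0))
    msg <- c(msg, "lambda weights must be non-negative")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (any(c(object@TU, object@TV, object@TW) < 0))
    msg <- c(msg, "thresholds must be non-negative")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@maxIters < 0L) msg <- c(msg, "maxIters must be >= 0")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (!object@varianceWeighting %in% c("as_written", "chi_square"))
    msg <- c(msg, "varianceWeighting must be 'as_written' or 'chi_square'")
  if (!object@l1Mode %in% c("subgradient", "proximal"))
    msg <- c(msg, "l1Mode must be 'subgradient' or 'proximal'")
  if (length(msg)) msg else TRUE
})

#' @param K,lambda1,lambda2,lambda3,beta,TU,TV,TW,learningRate,maxIters,warmStart,warmMaxIters,tol,window,varianceWeighting,l1Mode,seed
#'   see the class documentation.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(K = 10, lambda1 = 0.5, lambda2 = 0.5, lambda3 = 0.25,
                        beta = 2, TU = 0.5, TV = 0.25, TW = 0.001,
                        learningRate = 1e-2, maxIters = 250,
                        warmStart = TRUE, warmMaxIters = 200,
                        tol = 1e-5, window = 10,
                        varianceWeighting = "as_written",
                        l1Mode = "subgradient", seed = 1) {
  new("TrainConfig",
      K = as.integer(K), lambda1 = lambda1, lambda2 = lambda2,
      lambda3 = lambda3, beta = beta, TU = TU, TV = TV, TW = TW,
      learningRate = learningRate, maxIters = as.integer(maxIters),
      warmStart = warmStart, warmMaxIters = as.integer(warmMaxIters),
      tol = tol, window = as.integer(window),
      varianceWeighting = varianceWeighting, l1Mode = l1Mode,
      seed = as.integer(seed))
}

#' A trained Theia model
#'
#' Holds the non-negative module membership matrices \code{U} (I x K, miRNAs)
#' and \code{V} (J x K, genes), the signed regulation weight matrix \code{W}
#' (I x J), the configuration used, and the per-iteration training trace.
#' The interaction gate and edge matrix are derived on demand by
#' \code{\link{interactionGate}} and \code{\link{edgeMatrix}}.
#'
#' @slot U non-negative matrix I x K.
#' @slot V non-negative matrix J x K.
#' @slot W numeric matrix I x J; sign encodes regulation direction
#'   (negative = down-regulation).
#' @slot mirnaIds,geneIds feature identifiers.
#' @slot config the \code{\linkS4class{TrainConfig}} used.
#' @slot trace data.frame with one row per accepted iteration: total cost,
#'   the three component costs, the L1 term and the accepted step size.
#' @export
setClass("TheiaModel",
  representation(
    U = "matrix", V = "matrix", W = "matrix",
    mirnaIds = "character", geneIds = "character",
    config = "TrainConfig",
    trace = "data.frame"
  )
)

setValidity("TheiaModel", function(object) {
  msg <- character(0)
  if (any(object@U < 0) || any(object@V < 0))
    msg <- c(msg, "U and V must be non-negative")
  if (ncol(object@U) != ncol(object@V))
    msg <- c(msg, "U and V must have the same number of modules")
  if (!identical(dim(object@W), c(nrow(object@U), nrow(object@V))))
    msg <- c(msg, "W must be I x J")
  if (nrow(object@trace) > 1) {
    tot <- object@trace$total
    if (any(diff(tot) > 1e-9 * (1 + abs(tot[-length(tot)]))))
      msg <- c(msg, "training trace must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset generator configuration
#'
#' Parameters of the synthetic benchmark: problem dimensions, Gaussian
#' expression parameters, the regulation signal strength \code{pSignal}, the
#' relative putative false-positive rate \code{pFp}, the down-regulation
#' probability \code{pDown}, and the skew-normal parameters governing module
#' sizes and per-element module counts.
#'
#' Defaults are the standard benchmark conditions: N = 1000 samples, K = 10
#' modules, I = 50 miRNAs, J = 500 genes, \eqn{\mu_x = 3}, \eqn{\mu_y = 10},
#' \eqn{\sigma_x^2 = \sigma_y^2 = 1}, \code{pDown} = 0.8; module sizes
#' follow the SN(1, 1, 5) shape scaled to mean D/K and per-element module
#' counts follow SN(D/K, 10, 5) (see \code{\link{sampleMembership}}).
#'
#' @slot N,K,I,J problem dimensions.
#' @slot muX,muY baseline expression means.
#' @slot sigmaX2,sigmaY2 expression variances.
#' @slot pSignal regulation strength multiplier (>= 0).
#' @slot pFp relative false-positive rate of the putative matrix (>= 0).
#' @slot pDown probability that a true interaction is down-regulating.
#' @slot sizeXi,sizeOmega,sizeAlpha skew-normal parameters of module sizes.
#' @slot degreeOmega,degreeAlpha skew-normal scale/shape of per-element
#'   module counts (the location is D/K).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(
    N = "integer", K = "integer", I = "integer", J = "integer",
    muX = "numeric", muY = "numeric",
    sigmaX2 = "numeric", sigmaY2 = "numeric",
    pSignal = "numeric", pFp = "numeric", pDown = "numeric",
    sizeXi = "numeric", sizeOmega = "numeric", sizeAlpha = "numeric",
    degreeOmega = "numeric", degreeAlpha = "numeric",
    seed = "integer"
  ),
  prototype(
    N = 1000L, K = 10L, I = 50L, J = 500L,
    muX = 3, muY = 10, sigmaX2 = 1, sigmaY2 = 1,
    pSignal = 0.5, pFp = 0, pDown = 0.8,
    sizeXi = 1, sizeOmega = 1, sizeAlpha = 5,
    degreeOmega = 10, degreeAlpha = 5,
    seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (any(c(object@N, object@K, object@I, object@J) < 1L))
    msg <- c(msg, "N, K, I, J must be positive")
  if (object@I < 2L || object@J < 2L)
    msg <- c(msg, "need at least 2 miRNAs and 2 genes")
  if (any(c(object@sigmaX2, object@sigmaY2) <= 0))
    msg <- c(msg, "variances must be positive")
  if (object@pSignal < 0) msg <- c(msg, "pSignal must be >= 0")
  if (object@pFp < 0) msg <- c(msg, "pFp must be >= 0")
  if (object@pDown < 0 || object@pDown > 1)
    msg <- c(msg, "pDown must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param N,K,I,J,muX,muY,sigmaX2,sigmaY2,pSignal,pFp,pDown,sizeXi,sizeOmega,sizeAlpha,degreeOmega,degreeAlpha,seed
#'   see the class documentation.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(N = 1000, K = 10, I = 50, J = 500,
                      muX = 3, muY = 10, sigmaX2 = 1, sigmaY2 = 1,
                      pSignal = 0.5, pFp = 0, pDown = 0.8,
                      sizeXi = 1, sizeOmega = 1, sizeAlpha = 5,
                      degreeOmega = 10, degreeAlpha = 5, seed = 1) {
  new("SimConfig",
      N = as.integer(N), K = as.integer(K), I = as.integer(I),
      J = as.integer(J), muX = muX, muY = muY,
      sigmaX2 = sigmaX2, sigmaY2 = sigmaY2,
      pSignal = pSignal, pFp = pFp, pDown = pDown,
      sizeXi = sizeXi, sizeOmega = sizeOmega, sizeAlpha = sizeAlpha,
      degreeOmega = degreeOmega, degreeAlpha = degreeAlpha,
      seed = as.integer(seed))
}

#' Ground truth of a synthetic dataset
#'
#' @slot Utrue,Vtrue binary membership matrices (I x K and J x K).
#' @slot G signed ground-truth interaction matrix in \{-1, 0, 1\}^(I x J).
#' @slot bundle the generated \code{\linkS4class{ExpressionBundle}}.
#' @slot priors the generated \code{\linkS4class{InteractionPriors}}.
#' @slot config the \code{\linkS4class{SimConfig}} used.
#' @export
setClass("SyntheticTruth",
  representation(
    Utrue = "matrix", Vtrue = "matrix", G = "matrix",
    bundle = "ExpressionBundle", priors = "InteractionPriors",
    config = "SimConfig"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  if (!all(object@Utrue %in% c(0, 1)) || !all(object@Vtrue %in% c(0, 1)))
    msg <- c(msg, "Utrue and Vtrue must be binary")
  if (!all(object@G %in% c(-1, 0, 1)))
    msg <- c(msg, "G entries must lie in {-1, 0, 1}")
  shared <- (object@Utrue %*% t(object@Vtrue)) >= 1
  if (!identical(unname(object@G != 0), unname(shared)))
    msg <- c(msg, "G must be nonzero exactly where a module is shared")
  if (length(msg)) msg else TRUE
})

#' Metrics of one evaluation run
#'
#' @slot ari adjusted Rand index of true vs recovered comodules.
#' @slot precision,recall,f1 direction-aware interaction metrics.
#' @slot aupr area under the precision-recall curve.
#' @slot detectionRate fraction of validated interactions recovered
#'   (\code{NA} when no validated set was supplied).
#' @slot counts named integer vector (tp, fp, fn, tn).
#' @export
setClass("EvaluationReport",
  representation(
    ari = "numeric",
    precision = "numeric", recall = "numeric", f1 = "numeric",
    aupr = "numeric",
    detectionRate = "numeric",
    counts = "integer"
  ),
  prototype(ari = NA_real_, precision = NA_real_, recall = NA_real_,
            f1 = NA_real_, aupr = NA_real_, detectionRate = NA_real_,
            counts = integer(0))
)
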