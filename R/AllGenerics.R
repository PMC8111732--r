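#' @include AllClasses.R
NULL

#' Accessors for theia containers
#'
#' Small family of accessor generics: expression matrices, identifier
#' vectors, per-gene moments, prior matrices and model factors.
#'
#' @param object a theia S4 object.
#' @return the requested slot content (matrices carry dimnames).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaExpr", function(object) standardGeneric("mirnaExpr"))
#' @rdname accessors
#' @export
setGeneric("geneExpr", function(object) standardGeneric("geneExpr"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(object) standardGeneric("mirnaIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneMeans", function(object) standardGeneric("geneMeans"))
#' @rdname accessors
#' @export
setGeneric("geneVars", function(object) standardGeneric("geneVars"))
#' @rdname accessors
#' @export
setGeneric("putativeMatrix", function(object) standardGeneric("putativeMatrix"))
#' @rdname accessors
#' @export
setGeneric("ppiMatrix", function(object) standardGeneric("ppiMatrix"))
#' @rdname accessors
#' @export
setGeneric("mirnaMembership", function(object) standardGeneric("mirnaMembership"))
#' @rdname accessors
#' @export
setGeneric("geneMembership", function(object) standardGeneric("geneMembership"))
#' @rdname accessors
#' @export
setGeneric("regulationWeights", function(object) standardGeneric("regulationWeights"))
#' @rdname accessors
#' @export
setGeneric("trainingTrace", function(object) standardGeneric("trainingTrace"))
#' @rdname accessors
#' @export
setGeneric("trainConfig", function(object) standardGeneric("trainConfig"))
#' @rdname accessors
#' @export
setGeneric("trueInteractions", function(object) standardGeneric("trueInteractions"))

setMethod("mirnaExpr", "ExpressionBundle", function(object) {
  m <- object@X
  dimnames(m) <- list(object@sampleIds, object@mirnaIds)
  m
})
setMethod("geneExpr", "ExpressionBundle", function(object) {
  m <- object@Y
  dimnames(m) <- list(object@sampleIds, object@geneIds)
  m
})
setMethod("sampleIds", "ExpressionBundle", function(object) object@sampleIds)
setMethod("mirnaIds", "ExpressionBundle", function(object) object@mirnaIds)
setMethod("geneIds", "ExpressionBundle", function(object) object@geneIds)
setMethod("geneMeans", "ExpressionBundle", function(object) {
  stats::setNames(object@mu, object@geneIds)
})
setMethod("geneVars", "ExpressionBundle", function(object) {
  stats::setNames(object@sigma2, object@geneIds)
})

setMethod("mirnaIds", "InteractionPriors", function(object) object@mirnaIds)
setMethod("geneIds", "InteractionPriors", function(object) object@geneIds)
setMethod("putativeMatrix", "InteractionPriors", function(object) {
  m <- object@P
  dimnames(m) <- list(object@mirnaIds, object@geneIds)
  m
})
setMethod("ppiMatrix", "InteractionPriors", function(object) {
  m <- object@Q
  dimnames(m) <- list(object@geneIds, object@geneIds)
  m
})

setMethod("mirnaIds", "TheiaModel", function(object) object@mirnaIds)
setMethod("geneIds", "TheiaModel", function(object) object@geneIds)
setMethod("mirnaMembership", "TheiaModel", function(object) {
  m <- object@U
  rownames(m) <- object@mirnaIds
  m
})
setMethod("geneMembership", "TheiaModel", function(object) {
  m <- object@V
  rownames(m) <- object@geneIds
  m
})
setMethod("regulationWeights", "TheiaModel", function(object) {
  m <- object@W
  dimnames(m) <- list(object@mirnaIds, object@geneIds)
  m
})
setMethod("trainingTrace", "TheiaModel", function(object) object@trace)
setMethod("trainConfig", "TheiaModel", function(object) object@config)

setMethod("mirnaMembership", "SyntheticTruth", function(object) {
  m <- object@Utrue
  rownames(m) <- object@bundle@mirnaIds
  m
})
setMethod("geneMembership", "SyntheticTruth", function(object) {
  m <- object@Vtrue
  rownames(m) <- object@bundle@geneIds
  m
})
setMethod("trueInteractions", "SyntheticTruth", function(object) {
  m <- object@G
  dimnames(m) <- list(object@bundle@mirnaIds, object@bundle@geneIds)
  m
})

setMethod("show", "ExpressionBundle", function(object) {
  cat("ExpressionBundle:", nrow(object@X), "samples,",
      ncol(object@X), "miRNAs,", ncol(object@Y), "genes\n")
})

setMethod("show", "InteractionPriors", function(object) {
  cat("InteractionPriors:", nrow(object@P), "miRNAs x", ncol(object@P),
      "genes; |P| =", sum(object@P), "edges, |Q|/2 =",
      sum(object@Q) / 2, "PPI edges\n")
})

setMethod("show", "TheiaModel", function(object) {
  cat("TheiaModel: K =", ncol(object@U), "modules,",
      nrow(object@U), "miRNAs,", nrow(object@V), "genes\n")
  if (nrow(object@trace)) {
    last <- object@trace[nrow(object@trace), ]
    cat(sprintf("  %d accepted iterations, final total cost %.6g\n",
                nrow(object@trace), last$total))
  }
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", object@config@I, "miRNAs,", object@config@J,
      "genes, K =", object@config@K, "modules;",
      sum(object@G != 0), "true interactions (",
      round(100 * mean(object@G[object@G != 0] < 0), 1),
      "% down-regulating )\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: N=%d K=%d I=%d J=%d pSignal=%g pFp=%g pDown=%g seed=%d\n",
    object@N, object@K, object@I, object@J, object@pSignal, object@pFp,
    object@pDown, object@seed))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: K=%d lambda=(%g, %g, %g) beta=%g T=(%g, %g, %g) seed=%d\n",
    object@K, object@lambda1, object@lambda2, object@lambda3, object@beta,
    object@TU, object@TV, object@TW, object@seed))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  ARI        %.4f\n", object@ari))
  cat(sprintf("  precision  %.4f  recall %.4f  F1 %.4f\n",
              object@precision, object@recall, object@f1))
  cat(sprintf("  AUPR       %.4f\n", object@aupr))
  if (!is.na(object@detectionRate))
    cat(sprintf("  detection  %.4f\n", object@detectionRate))
  if (length(object@counts))
    cat("  counts     ", paste(names(object@counts), object@counts,
                               sep = "=", collapse = " "), "\n")
})
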