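#' Extract regulatory comodules from membership matrices
#'
#' MiRNA i joins module k when \eqn{u_{ik} > T_U}; gene j joins when
#' \eqn{v_{jk} > T_V}.  Membership is many-to-many: an element may appear in
#' several comodules.  Modules with fewer than \code{minMirnas} miRNAs or
#' fewer than \code{minGenes} genes are discarded (default 2 and 2).
#'
#' @param U non-negative matrix I x K, or a \code{\linkS4class{TheiaModel}}
#'   (in which case \code{V} and the thresholds default from the model).
#' @param V non-negative matrix J x K.
#' @param TU,TV membership cutoffs.
#' @param mirnaIds,geneIds identifiers; default to the row names.
#' @param minMirnas,minGenes minimum module sizes after thresholding.
#' @return list of comodules; each is a list with \code{index} (column of
#'   U/V), \code{mirnas} and \code{genes} (character vectors).
#' @export
assignComodules <- function(U, V = NULL, TU = 0.5, TV = 0.25,
                            mirnaIds = rownames(U), geneIds = rownames(V),
                            minMirnas = 2L, minGenes = 2L) {
  if (is(U, "TheiaModel")) {
    model <- U
    U <- mirnaMembership(model)
    if (is.null(V)) V <- geneMembership(model)
    if (missing(TU)) TU <- model@config@TU
    if (missing(TV)) TV <- model@config@TV
    mirnaIds <- rownames(U)
    geneIds <- rownames(V)
  }
  stopifnot(TU >= 0, TV >= 0, ncol(U) == ncol(V))
  if (is.null(mirnaIds)) mirnaIds <- sprintf("mir%03d", seq_len(nrow(U)))
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_len(nrow(V)))
  out <- list()
  for (k in seq_len(ncol(U))) {
    m <- mirnaIds[U[, k] > TU]
    g <- geneIds[V[, k] > TV]
    if (length(m) >= minMirnas && length(g) >= minGenes)
      out[[length(out) + 1L]] <- list(index = k, mirnas = m, genes = g)
  }
  out
}

#' Regulatory network edge matrix
#'
#' \eqn{e_{ij} = s_{ij} p_{ij} w_{ij}}: the regulation weight filtered by
#' the gate and by the putative prior, so edges outside the support of P are
#' exactly zero.
#'
#' @param S gate matrix I x J.
#' @param P binary putative matrix I x J.
#' @param W regulation weight matrix I x J.
#' @return numeric matrix I x J.
#' @export
edgeMatrix <- function(S, P, W) {
  if (!identical(dim(S), dim(P)) || !identical(dim(S), dim(W)))
    stop("S, P and W must share the same I x J shape")
  S * P * W
}

#' Call individual miRNA-gene interactions
#'
#' An interaction is called where \eqn{|e_{ij}| > T_W} (default; most
#' regulation is down-regulating, so the edge value is typically negative
#' and thresholding the magnitude keeps those calls).  The literal one-sided
#' rule \eqn{e_{ij} > T_W} is available with \code{mode = "literal"}.
#' Direction comes from the sign of \eqn{w_{ij}}: positive = up-regulation.
#'
#' @param E edge matrix from \code{\link{edgeMatrix}}.
#' @param W regulation weight matrix.
#' @param TW calling threshold (>= 0).
#' @param S optional gate matrix, carried through to the output.
#' @param mode \code{"absolute"} thresholds \eqn{|e_{ij}|};
#'   \code{"literal"} thresholds the signed value.
#' @param mirnaIds,geneIds identifiers; default to the dimnames of \code{E}.
#' @return data.frame with columns mirna, gene, weight, gate, edge,
#'   direction ("up"/"down"), sorted by decreasing \eqn{|e|}, ties broken
#'   by (mirna, gene).
#' @export
callInteractions <- function(E, W, TW = 0.001, S = NULL,
                             mode = c("absolute", "literal"),
                             mirnaIds = rownames(E), geneIds = colnames(E)) {
  mode <- match.arg(mode)
  stopifnot(TW >= 0, identical(dim(E), dim(W)))
  if (is.null(mirnaIds)) mirnaIds <- sprintf("mir%03d", seq_len(nrow(E)))
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_len(ncol(E)))
  keep <- if (mode == "absolute") abs(E) > TW else E > TW
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(
    mirna = mirnaIds[idx[, 1]],
    gene = geneIds[idx[, 2]],
    weight = W[idx],
    gate = if (is.null(S)) rep(NA_real_, nrow(idx)) else S[idx],
    edge = E[idx],
    direction = ifelse(W[idx] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  df <- df[order(-abs(df$edge), df$mirna, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Derive comodules and interaction calls from a fitted model
#'
#' Convenience wrapper applying \code{\link{assignComodules}},
#' \code{\link{interactionGate}}, \code{\link{edgeMatrix}} and
#' \code{\link{callInteractions}} with the thresholds stored in the model's
#' configuration.
#'
#' @param model a \code{\linkS4class{TheiaModel}}.
#' @param priors the \code{\linkS4class{InteractionPriors}} used in
#'   training.
#' @param TU,TV,TW optional threshold overrides.
#' @param mode edge-calling mode, see \code{\link{callInteractions}}.
#' @return list with \code{comodules}, \code{calls}, and the derived
#'   matrices \code{S} and \code{E}.
#' @export
theiaPostprocess <- function(model, priors, TU = model@config@TU,
                             TV = model@config@TV, TW = model@config@TW,
                             mode = "absolute") {
  stopifnot(is(model, "TheiaModel"), is(priors, "InteractionPriors"))
  S <- interactionGate(model@U, model@V, model@config@beta)
  E <- edgeMatrix(S, priors@P, model@W)
  dimnames(E) <- list(model@mirnaIds, model@geneIds)
  list(
    comodules = assignComodules(mirnaMembership(model),
                                geneMembership(model), TU, TV),
    calls = callInteractions(E, model@W, TW, S, mode = mode),
    S = S, E = E)
}
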