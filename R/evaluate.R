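# Pair-counting adjusted Rand index of two hard label vectors.
# Standard contingency-table formula with sum-of-choose terms.
.ari <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  tot <- choose(length(a), 2)
  expected <- si * sj / tot
  mx <- (si + sj) / 2
  if (mx == expected) return(ifelse(sij == expected, 1, 0))
  (sij - expected) / (mx - expected)
}

#' Hard module labels from a membership matrix
#'
#' Flattens possibly overlapping memberships to a partition: each element is
#' assigned to its argmax module when that membership exceeds the threshold,
#' and to a background label 0 otherwise.  Argmax ties resolve to the first
#' module.
#'
#' @param M membership matrix D x K (binary or continuous).
#' @param threshold membership cutoff.
#' @return integer vector of length D with values in 0..K.
#' @export
membershipLabels <- function(M, threshold = 0.5) {
  if (ncol(M) == 0) return(rep(0L, nrow(M)))
  best <- max.col(M, ties.method = "first")
  val <- M[cbind(seq_len(nrow(M)), best)]
  ifelse(val > threshold, best, 0L)
}

#' Adjusted Rand index between true and recovered comodules
#'
#' Compares the comodule structure of two membership-matrix pairs over the
#' joint universe of miRNAs and genes.  Because the ARI is defined on
#' partitions while comodule membership is many-to-many, the memberships are
#' reduced to a hard partition first.  Two reductions are offered:
#' \code{"argmax"} (default) assigns each element to its strongest module
#' above threshold, with a shared background cluster for unassigned
#' elements; \code{"comembership"} compares the pairwise co-membership
#' relations directly, chance-corrected from the pair marginals, as a
#' sensitivity analysis for heavily overlapping module structures.
#'
#' @param Utrue,Vtrue reference membership matrices (binary, I x K and
#'   J x K).
#' @param U,V recovered membership matrices (I x K', J x K'; K' need not
#'   equal K).
#' @param TU,TV thresholds applied to the recovered memberships.
#' @param trueThreshold threshold applied to the reference memberships.
#' @param mode \code{"argmax"} or \code{"comembership"}.
#' @return scalar in [-1, 1]; 1 for a perfect match, about 0 for random
#'   assignment.
#' @export
comoduleARI <- function(Utrue, Vtrue, U, V, TU = 0.5, TV = 0.5,
                        trueThreshold = 0.5,
                        mode = c("argmax", "comembership")) {
  mode <- match.arg(mode)
  if (nrow(Utrue) + nrow(Vtrue) == 0) stop("empty universe")
  stopifnot(nrow(U) == nrow(Utrue), nrow(V) == nrow(Vtrue))
  if (mode == "argmax") {
    labsTrue <- c(membershipLabels(Utrue, trueThreshold),
                  membershipLabels(Vtrue, trueThreshold))
    labsPred <- c(membershipLabels(U, TU), membershipLabels(V, TV))
    .ari(labsTrue, labsPred)
  } else {
    co <- function(A, B, ta, tb) {
      memA <- (A > ta) + 0
      memB <- (B > tb) + 0
      M <- rbind(memA, memB)
      shared <- tcrossprod(M) >= 1
      shared[upper.tri(shared)]
    }
    c1 <- co(Utrue, Vtrue, trueThreshold, trueThreshold)
    c2 <- co(U, V, TU, TV)
    ri <- mean(c1 == c2)
    p1 <- mean(c1); p2 <- mean(c2)
    expected <- p1 * p2 + (1 - p1) * (1 - p2)
    if (expected >= 1) return(ifelse(ri == 1, 1, 0))
    (ri - expected) / (1 - expected)
  }
}

#' Direction-aware confusion counts and F1 of interaction calls
#'
#' A call is a true positive only when both the interaction and its
#' direction are correct: the pair has \eqn{g_{ij} \ne 0} and the call's
#' sign matches.  A call where \eqn{g_{ij} = 0} is a false positive; an
#' uncalled pair with \eqn{g_{ij} = 0} is a true negative; every remaining
#' case, including a call with the wrong sign, is a false negative.  The
#' four counts therefore always sum to I*J.
#'
#' @param G ground-truth signed matrix in \{-1, 0, 1\} with dimnames.
#' @param calls data.frame from \code{\link{callInteractions}} (columns
#'   mirna, gene, direction), or a signed called matrix of the same shape
#'   as G.
#' @return an \code{\linkS4class{EvaluationReport}} with precision, recall,
#'   f1 and the counts filled in.
#' @export
interactionF1 <- function(G, calls) {
  if (is.data.frame(calls)) {
    if (anyDuplicated(paste(calls$mirna, calls$gene, sep = "\r")))
      stop("duplicate calls for one miRNA-gene pair")
    C <- matrix(0, nrow(G), ncol(G), dimnames = dimnames(G))
    if (nrow(calls)) {
      ri <- match(calls$mirna, rownames(G))
      ci <- match(calls$gene, colnames(G))
      if (anyNA(ri) || anyNA(ci))
        stop("calls name ids absent from the truth matrix")
      C[cbind(ri, ci)] <- ifelse(calls$direction == "up", 1, -1)
    }
  } else {
    C <- calls
    stopifnot(identical(dim(C), dim(G)))
  }
  tp <- sum(C != 0 & C == G & G != 0)
  fp <- sum(C != 0 & G == 0)
  tn <- sum(C == 0 & G == 0)
  fn <- length(G) - tp - fp - tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  new("EvaluationReport", precision = precision, recall = recall, f1 = f1,
      counts = c(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)))
}

#' Precision-recall curve and AUPR over the edge-calling threshold
#'
#' Sweeps the calling threshold over the magnitudes of the edge matrix:
#' at each threshold t the calls are the pairs with \eqn{|e_{ij}| > t},
#' directed by the sign of \eqn{w_{ij}}, and counted direction-aware as in
#' \code{\link{interactionF1}}.  The area under the recall-sorted curve is
#' integrated by the trapezoid rule, anchored at (recall 0, precision 1).
#'
#' @param E edge matrix I x J.
#' @param W regulation weight matrix I x J.
#' @param G ground-truth signed matrix.
#' @param thresholds optional increasing threshold vector; defaults to all
#'   distinct values of \eqn{|e_{ij}|}.
#' @return list with \code{curve} (data.frame threshold, precision, recall)
#'   and scalar \code{aupr}.
#' @export
precisionRecall <- function(E, W, G, thresholds = NULL) {
  stopifnot(identical(dim(E), dim(G)), identical(dim(W), dim(G)))
  ae <- abs(as.vector(E))
  sgnOk <- (sign(W) == G) & (G != 0)  # call would be a TP if made
  isNull <- as.vector(G == 0)
  nPos <- sum(G != 0)
  if (is.null(thresholds)) thresholds <- sort(unique(ae))
  thresholds <- sort(thresholds)
  ord <- order(ae, decreasing = TRUE)
  aeSorted <- ae[ord]
  cumTp <- cumsum(as.vector(sgnOk)[ord])
  cumFp <- cumsum(isNull[ord])
  n <- length(ae)
  prec <- rec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    ncalls <- sum(aeSorted > thresholds[i])
    tp <- if (ncalls > 0) cumTp[ncalls] else 0
    fp <- if (ncalls > 0) cumFp[ncalls] else 0
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
    rec[i] <- if (nPos > 0) tp / nPos else 0
  }
  curve <- data.frame(threshold = thresholds, precision = prec,
                      recall = rec)
  o <- order(rec)
  r <- c(0, rec[o])
  p <- c(1, prec[o])
  aupr <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = curve, aupr = aupr)
}

#' Detection rate against a validated interaction set
#'
#' Fraction of externally validated interactions recovered by the caller.
#' No precision is reported: validated collections are incomplete, so an
#' unvalidated call cannot be scored as a false positive.
#'
#' @param validated data.frame with columns mirna and gene, or a character
#'   vector of "mirna:gene" keys.
#' @param calls data.frame from \code{\link{callInteractions}}.
#' @return scalar in [0, 1].
#' @export
detectionRate <- function(validated, calls) {
  if (is.data.frame(validated))
    validated <- paste(validated$mirna, validated$gene, sep = ":")
  validated <- unique(validated)
  if (length(validated) == 0) stop("empty validated set")
  called <- unique(paste(calls$mirna, calls$gene, sep = ":"))
  sum(validated %in% called) / length(validated)
}

#' Mean of the top-k absolute correlations among interacting pairs
#'
#' For every interacting pair (nonzero entry of G) the Pearson correlation
#' between the miRNA's and the gene's expression is computed across
#' samples; the statistic is the mean of the \code{topK} largest absolute
#' values.  Absolute values are used because positive correlations indicate
#' up-regulation and negative ones down-regulation.
#'
#' @param bundle an \code{\linkS4class{ExpressionBundle}}.
#' @param G signed interaction matrix I x J.
#' @param topK number of top pairs averaged (default 10).
#' @return scalar in [0, 1].
#' @export
pccTopMean <- function(bundle, G, topK = 10) {
  idx <- which(G != 0, arr.ind = TRUE)
  if (nrow(idx) < topK)
    stop("only ", nrow(idx), " interacting pairs; need at least ", topK)
  cc <- stats::cor(bundle@X, bundle@Y)
  vals <- abs(cc[idx])
  mean(sort(vals, decreasing = TRUE)[seq_len(topK)])
}

#' Evaluate a fitted model against synthetic ground truth
#'
#' Computes comodule ARI, direction-aware precision/recall/F1 of the called
#' interactions, and AUPR in one pass.  Thresholds default to the model
#' configuration; for synthetic benchmarks both membership cutoffs are
#' typically set to 0.5.
#'
#' @param model a \code{\linkS4class{TheiaModel}}.
#' @param truth a \code{\linkS4class{SyntheticTruth}}.
#' @param TU,TV,TW threshold overrides.
#' @param validated optional validated interaction set for the detection
#'   rate.
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @export
evaluateModel <- function(model, truth, TU = model@config@TU,
                          TV = model@config@TV, TW = model@config@TW,
                          validated = NULL) {
  stopifnot(is(model, "TheiaModel"), is(truth, "SyntheticTruth"))
  post <- theiaPostprocess(model, truth@priors, TU = TU, TV = TV, TW = TW)
  G <- trueInteractions(truth)
  rep1 <- interactionF1(G, post$calls)
  ari <- comoduleARI(truth@Utrue, truth@Vtrue, model@U, model@V,
                     TU = TU, TV = TV)
  pr <- precisionRecall(post$E, model@W, G)
  dr <- if (is.null(validated)) NA_real_
        else detectionRate(validated, post$calls)
  new("EvaluationReport", ari = ari, precision = rep1@precision,
      recall = rep1@recall, f1 = rep1@f1, aupr = pr$aupr,
      detectionRate = dr, counts = rep1@counts)
}

#' Simulate, fit and evaluate over a (pSignal, pFp) grid
#'
#' For every grid cell and seed: generate a synthetic dataset, fit the
#' model, and record ARI and direction-aware F1.  Raw per-seed values are
#' returned in long format; Gaussian smoothing (see
#' \code{\link{smoothGrid}}) is a display transform only and is never
#' applied to the stored values.  A failing cell is recorded with NA
#' metrics and the sweep continues.
#'
#' @param pSignalGrid,pFpGrid numeric axes (defaults: 0 to 1 by 0.05 and
#'   0 to 2 by 0.05, the 21 x 41 = 861-cell reference grid).
#' @param simConfig template \code{\linkS4class{SimConfig}}; its pSignal,
#'   pFp and seed are overridden per cell.
#' @param trainConfig \code{\linkS4class{TrainConfig}} used for every fit.
#' @param nSeeds replicate seeds per cell.
#' @param seeds optional explicit seed vector (length nSeeds).
#' @param TU,TV,TW evaluation thresholds (default 0.5/0.5 membership
#'   cutoffs of the synthetic benchmark and the trainConfig's TW).
#' @param verbose print one line per cell.
#' @return data.frame with columns pSignal, pFp, seed, ari, f1, aupr.
#' @export
runSweep <- function(pSignalGrid = seq(0, 1, by = 0.05),
                     pFpGrid = seq(0, 2, by = 0.05),
                     simConfig = SimConfig(), trainConfig = TrainConfig(),
                     nSeeds = 5, seeds = NULL,
                     TU = 0.5, TV = 0.5, TW = trainConfig@TW,
                     verbose = FALSE) {
  if (is.null(seeds)) seeds <- seq_len(nSeeds)
  grid <- expand.grid(pSignal = pSignalGrid, pFp = pFpGrid, seed = seeds)
  res <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sc <- simConfig
    sc@pSignal <- grid$pSignal[r]
    sc@pFp <- grid$pFp[r]
    sc@seed <- as.integer(grid$seed[r])
    tc <- trainConfig
    tc@seed <- as.integer(grid$seed[r])
    rec <- tryCatch({
      truth <- simulateDataset(sc)
      model <- theiaFit(truth@bundle, truth@priors, tc)
      ev <- evaluateModel(model, truth, TU = TU, TV = TV, TW = TW)
      c(ari = ev@ari, f1 = ev@f1, aupr = ev@aupr)
    }, error = function(e) {
      warning("sweep cell failed (pSignal=", sc@pSignal, ", pFp=", sc@pFp,
              ", seed=", sc@seed, "): ", conditionMessage(e))
      c(ari = NA_real_, f1 = NA_real_, aupr = NA_real_)
    })
    if (verbose)
      message(sprintf("pSignal=%g pFp=%g seed=%d ari=%.3f f1=%.3f",
                      grid$pSignal[r], grid$pFp[r], grid$seed[r],
                      rec["ari"], rec["f1"]))
    res[[r]] <- rec
  }
  cbind(grid, do.call(rbind, res))
}

#' Gaussian smoothing of a metric grid (display only)
#'
#' Convolves a matrix of per-cell metric values with an isotropic Gaussian
#' kernel (sd in grid cells), renormalizing at the borders.  Intended for
#' contour displays of sweep results; raw values should be kept unsmoothed.
#'
#' @param M numeric matrix of cell values.
#' @param sigma kernel standard deviation in cells (default 0.5).
#' @return smoothed matrix of the same shape.
#' @export
smoothGrid <- function(M, sigma = 0.5) {
  r <- max(1L, ceiling(3 * sigma))
  ax <- (-r):r
  k <- outer(stats::dnorm(ax, sd = sigma), stats::dnorm(ax, sd = sigma))
  out <- matrix(0, nrow(M), ncol(M))
  wsum <- matrix(0, nrow(M), ncol(M))
  for (di in ax) for (dj in ax) {
    w <- k[di + r + 1L, dj + r + 1L]
    si <- seq_len(nrow(M)) + di
    sj <- seq_len(ncol(M)) + dj
    ok_i <- si >= 1 & si <= nrow(M)
    ok_j <- sj >= 1 & sj <= ncol(M)
    out[ok_i, ok_j] <- out[ok_i, ok_j] + w * M[si[ok_i], sj[ok_j]]
    wsum[ok_i, ok_j] <- wsum[ok_i, ok_j] + w
  }
  out / wsum
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, member ids.
#'
#' @param path path to the .gmt file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Fisher exact enrichment of modules in a set collection
#'
#' One-sided (over-representation) Fisher exact test of every
#' (module, set) overlap against the 2 x 2 contingency table over the
#' universe, with Benjamini-Hochberg correction across all tests.  Sets
#' outside \code{sizeRange} (when given) are dropped before testing.
#'
#' @param modules named list of character vectors (e.g. the gene members of
#'   each comodule).
#' @param collection named list of character vectors (e.g. read with
#'   \code{\link{readGmt}}).
#' @param universe character vector of all testable ids.
#' @param sizeRange optional c(min, max) member-count filter applied to the
#'   collection after intersecting with the universe (e.g. c(5, 300)).
#' @param qCutoff significance flag threshold (default 0.05).
#' @return data.frame with module, set, overlap, moduleSize, setSize,
#'   pValue, qValue, significant; sorted by qValue.
#' @export
fisherEnrichment <- function(modules, collection, universe,
                             sizeRange = NULL, qCutoff = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (length(collection) == 0) stop("empty set collection")
  if (is.null(names(modules)))
    names(modules) <- sprintf("module%d", seq_along(modules))
  collection <- lapply(collection, function(s) intersect(s, universe))
  if (!is.null(sizeRange)) {
    n <- lengths(collection)
    collection <- collection[n >= sizeRange[1] & n <= sizeRange[2]]
    if (length(collection) == 0)
      stop("no sets left after size filtering")
  }
  modules <- lapply(modules, function(m) intersect(m, universe))
  rows <- list()
  for (mn in names(modules)) for (sn in names(collection)) {
    m <- modules[[mn]]; s <- collection[[sn]]
    both <- length(intersect(m, s))
    tab <- matrix(c(both, length(m) - both,
                    length(s) - both,
                    length(universe) - length(m) - length(s) + both), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      module = mn, set = sn, overlap = both,
      moduleSize = length(m), setSize = length(s),
      pValue = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$qValue <- stats::p.adjust(out$pValue, method = "BH")
  out$significant <- out$qValue < qCutoff
  out[order(out$qValue, out$pValue), , drop = FALSE]
}
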