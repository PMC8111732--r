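# Run-directory plumbing shared by the pipeline commands: every command
# writes its outputs plus a single machine-readable manifest into one
# directory and refuses to clobber an existing run unless told to.

.prepareRunDir <- function(dir, overwrite = FALSE) {
  if (dir.exists(dir)) {
    if (!overwrite && length(list.files(dir)))
      stop("output directory '", dir,
           "' is not empty; use overwrite = TRUE to replace it")
  } else {
    dir.create(dir, recursive = TRUE)
  }
  invisible(dir)
}

.writeManifest <- function(dir, command, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    tool = "theia",
    version = as.character(utils::packageVersion("theia")),
    seed = seed,
    config = config,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.configAsList <- function(cfg) {
  slots <- slotNames(class(cfg))
  stats::setNames(lapply(slots, function(s) slot(cfg, s)), slots)
}

#' Write a synthetic dataset to a run directory
#'
#' Emits the four model inputs in the package's tabular formats (X and Y as
#' samples-by-features TSV, P and Q as two-column edge lists) plus the
#' ground-truth files (G as a signed edge list, the true memberships in
#' long format) and a manifest echoing the generator configuration.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param dir output directory.
#' @param overwrite replace an existing non-empty directory.
#' @return the generated \code{\linkS4class{SyntheticTruth}}, invisibly.
#' @export
runSimulate <- function(config = SimConfig(), dir, overwrite = FALSE) {
  .prepareRunDir(dir, overwrite)
  truth <- simulateDataset(config)
  writeExpression(mirnaExpr(truth@bundle), file.path(dir, "X.tsv"))
  writeExpression(geneExpr(truth@bundle), file.path(dir, "Y.tsv"))
  writeEdgeList(putativeMatrix(truth@priors), file.path(dir, "P.tsv"))
  writeEdgeList(ppiMatrix(truth@priors), file.path(dir, "Q.tsv"),
                symmetric = TRUE)
  writeSignedEdgeList(trueInteractions(truth), file.path(dir, "G_true.tsv"))
  writeMembership(mirnaMembership(truth), file.path(dir, "U_true.tsv"))
  writeMembership(geneMembership(truth), file.path(dir, "V_true.tsv"))
  .writeManifest(dir, "simulate", .configAsList(config), config@seed)
  invisible(truth)
}

#' Load a dataset directory
#'
#' Reads the files written by \code{\link{runSimulate}} (or prepared by the
#' user in the same formats) back into aligned in-memory objects.  Ids are
#' aligned by name, so the on-disk row order is irrelevant.
#'
#' @param dir dataset directory containing X.tsv, Y.tsv, P.tsv, Q.tsv.
#' @return list with \code{bundle}, \code{priors}, and (when the truth
#'   files are present) \code{G}, \code{Utrue}, \code{Vtrue}.
#' @export
readDataset <- function(dir) {
  X <- readExpression(file.path(dir, "X.tsv"))
  Y <- readExpression(file.path(dir, "Y.tsv"))
  Y <- Y[rownames(X), , drop = FALSE]
  bundle <- ExpressionBundle(X, Y)
  P <- readEdgeList(file.path(dir, "P.tsv"), bundle@mirnaIds,
                    bundle@geneIds)
  Q <- readEdgeList(file.path(dir, "Q.tsv"), bundle@geneIds,
                    bundle@geneIds, symmetric = TRUE)
  out <- list(bundle = bundle, priors = InteractionPriors(P, Q))
  gPath <- file.path(dir, "G_true.tsv")
  if (file.exists(gPath)) {
    out$G <- readSignedEdgeList(gPath, bundle@mirnaIds, bundle@geneIds)
    mf <- file.path(dir, "manifest.json")
    K <- if (file.exists(mf))
      jsonlite::read_json(mf)$config$K else NULL
    if (!is.null(K)) {
      out$Utrue <- readMembership(file.path(dir, "U_true.tsv"),
                                  bundle@mirnaIds, K)
      out$Vtrue <- readMembership(file.path(dir, "V_true.tsv"),
                                  bundle@geneIds, K)
    }
  }
  out
}

#' Train a model from a dataset directory
#'
#' Loads the dataset, fits the joint model, and writes the learned matrices
#' (U, V, W as TSV), the comodules and interaction calls at the configured
#' thresholds, the training trace, and a manifest.
#'
#' @param datasetDir directory written by \code{\link{runSimulate}} or in
#'   the same formats.
#' @param dir output directory.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @param overwrite replace an existing non-empty directory.
#' @return the fitted \code{\linkS4class{TheiaModel}}, invisibly.
#' @export
runTrain <- function(datasetDir, dir, config = TrainConfig(),
                     overwrite = FALSE) {
  .prepareRunDir(dir, overwrite)
  ds <- readDataset(datasetDir)
  model <- theiaFit(ds$bundle, ds$priors, config)
  writeMembership(mirnaMembership(model), file.path(dir, "U.tsv"))
  writeMembership(geneMembership(model), file.path(dir, "V.tsv"))
  W <- regulationWeights(model)
  utils::write.table(
    data.frame(mirna = rownames(W)[row(W)[W != 0]],
               gene = colnames(W)[col(W)[W != 0]],
               weight = W[W != 0]),
    file.path(dir, "W.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trainingTrace(model), file.path(dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  post <- theiaPostprocess(model, ds$priors)
  co <- post$comodules
  coDf <- do.call(rbind, lapply(co, function(cm) {
    data.frame(module = cm$index,
               memberType = c(rep("mirna", length(cm$mirnas)),
                              rep("gene", length(cm$genes))),
               member = c(cm$mirnas, cm$genes), stringsAsFactors = FALSE)
  }))
  if (is.null(coDf))
    coDf <- data.frame(module = integer(0), memberType = character(0),
                       member = character(0))
  utils::write.table(coDf, file.path(dir, "comodules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(post$calls, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(dir, "train", .configAsList(config), config@seed,
                 inputs = file.path(datasetDir,
                                    c("X.tsv", "Y.tsv", "P.tsv", "Q.tsv")))
  invisible(model)
}

# Rebuild a TheiaModel from a model run directory.
.readModel <- function(modelDir, bundle) {
  mf <- jsonlite::read_json(file.path(modelDir, "manifest.json"))
  cfgList <- mf$config
  cfg <- TrainConfig(
    K = cfgList$K, lambda1 = cfgList$lambda1, lambda2 = cfgList$lambda2,
    lambda3 = cfgList$lambda3, beta = cfgList$beta, TU = cfgList$TU,
    TV = cfgList$TV, TW = cfgList$TW, learningRate = cfgList$learningRate,
    maxIters = cfgList$maxIters, warmStart = cfgList$warmStart,
    warmMaxIters = cfgList$warmMaxIters, tol = cfgList$tol,
    window = cfgList$window, varianceWeighting = cfgList$varianceWeighting,
    l1Mode = cfgList$l1Mode, seed = cfgList$seed)
  U <- readMembership(file.path(modelDir, "U.tsv"), bundle@mirnaIds, cfg@K)
  V <- readMembership(file.path(modelDir, "V.tsv"), bundle@geneIds, cfg@K)
  wDf <- utils::read.delim(file.path(modelDir, "W.tsv"),
                           stringsAsFactors = FALSE)
  W <- matrix(0, nrow(U), nrow(V))
  if (nrow(wDf))
    W[cbind(match(wDf$mirna, bundle@mirnaIds),
            match(wDf$gene, bundle@geneIds))] <- wDf$weight
  new("TheiaModel", U = unname(U), V = unname(V), W = W,
      mirnaIds = bundle@mirnaIds, geneIds = bundle@geneIds, config = cfg,
      trace = data.frame(iteration = integer(0), total = numeric(0),
                         jw = numeric(0), ju = numeric(0), jv = numeric(0),
                         l1 = numeric(0), step = numeric(0)))
}

#' Evaluate a trained model run against a dataset's ground truth
#'
#' Reloads the model matrices and the dataset (including the truth files),
#' recomputes comodules and calls at the stored thresholds, and writes an
#' evaluation report JSON.
#'
#' @param modelDir directory written by \code{\link{runTrain}}.
#' @param datasetDir dataset directory holding the ground truth.
#' @param reportPath output JSON path (default report.json inside
#'   \code{modelDir}).
#' @param TU,TV evaluation membership cutoffs (default 0.5/0.5, the
#'   synthetic-benchmark convention).
#' @return the \code{\linkS4class{EvaluationReport}}, invisibly.
#' @export
runEvaluate <- function(modelDir, datasetDir,
                        reportPath = file.path(modelDir, "report.json"),
                        TU = 0.5, TV = 0.5) {
  ds <- readDataset(datasetDir)
  if (is.null(ds$G))
    stop("dataset directory '", datasetDir, "' has no ground truth")
  model <- .readModel(modelDir, ds$bundle)
  post <- theiaPostprocess(model, ds$priors, TU = TU, TV = TV)
  G <- ds$G
  rep1 <- interactionF1(G, post$calls)
  ari <- comoduleARI(ds$Utrue, ds$Vtrue, model@U, model@V, TU = TU, TV = TV)
  pr <- precisionRecall(post$E, model@W, unname(G))
  report <- new("EvaluationReport", ari = ari, precision = rep1@precision,
                recall = rep1@recall, f1 = rep1@f1, aupr = pr$aupr,
                counts = rep1@counts)
  jsonlite::write_json(
    list(ari = report@ari, precision = report@precision,
         recall = report@recall, f1 = report@f1, aupr = report@aupr,
         counts = as.list(report@counts)),
    reportPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run a (pSignal, pFp) sweep and write long-format results
#'
#' @param pSignalGrid,pFpGrid numeric axes.
#' @param dir output directory for sweep.tsv and the manifest.
#' @param simConfig,trainConfig templates, see \code{\link{runSweep}}.
#' @param nSeeds replicate seeds per cell.
#' @param overwrite replace an existing non-empty directory.
#' @return the sweep data.frame, invisibly.
#' @export
runSweepDir <- function(pSignalGrid, pFpGrid, dir,
                        simConfig = SimConfig(),
                        trainConfig = TrainConfig(), nSeeds = 5,
                        overwrite = FALSE) {
  .prepareRunDir(dir, overwrite)
  sweep <- runSweep(pSignalGrid, pFpGrid, simConfig, trainConfig, nSeeds)
  utils::write.table(sweep, file.path(dir, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(dir, "sweep",
                 list(pSignalGrid = pSignalGrid, pFpGrid = pFpGrid,
                      nSeeds = nSeeds, sim = .configAsList(simConfig),
                      train = .configAsList(trainConfig)),
                 simConfig@seed)
  invisible(sweep)
}

#' Enrichment of comodules from a run directory
#'
#' Reads a comodules.tsv (as written by \code{\link{runTrain}}) and a GMT
#' collection, tests each module's gene members for over-representation,
#' and writes the q-value table.
#'
#' @param comodulesPath path to comodules.tsv.
#' @param gmtPath path to the GMT set collection.
#' @param outPath output TSV.
#' @param universe character vector of testable gene ids.
#' @param sizeRange optional set-size filter, e.g. c(5, 300).
#' @return the enrichment data.frame, invisibly.
#' @export
runEnrich <- function(comodulesPath, gmtPath, outPath, universe,
                      sizeRange = NULL) {
  co <- utils::read.delim(comodulesPath, stringsAsFactors = FALSE)
  co <- co[co$memberType == "gene", , drop = FALSE]
  modules <- split(co$member, co$module)
  names(modules) <- sprintf("module%s", names(modules))
  enr <- fisherEnrichment(modules, readGmt(gmtPath), universe,
                          sizeRange = sizeRange)
  utils::write.table(enr, outPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(enr)
}
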