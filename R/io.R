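#' Read a samples-by-features expression table
#'
#' Parses a TSV whose header row names the features and whose first column
#' holds sample identifiers; the body must be numeric.  The orientation is
#' fixed as samples x features, matching \eqn{X \in R^{N \times I}} and
#' \eqn{Y \in R^{N \times J}}.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with sample ids as row names and feature ids as
#'   column names.
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("expression file '", path, "' needs a header row and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (length(header) < 2)
    stop("missing header: expected sample-id column plus feature ids")
  featureIds <- header[-1]
  if (anyDuplicated(featureIds))
    stop("duplicate feature id in header: ",
         featureIds[duplicated(featureIds)][1])
  nf <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != nf))
    stop("ragged row ", which(widths != nf)[1] + 1L, ": expected ", nf,
         " fields, found ", widths[widths != nf][1])
  sampleIds <- trimws(vapply(body, `[[`, "", 1L))
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE)))
  if (anyNA(vals))
    stop("non-numeric cell in expression body of '", path, "'")
  M <- matrix(vals, nrow = length(body), ncol = nf - 1L, byrow = TRUE,
              dimnames = list(sampleIds, featureIds))
  M
}

#' Write a samples-by-features expression table
#'
#' Inverse of \code{\link{readExpression}} up to floating-point formatting.
#'
#' @param M numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name of the leading sample-id column.
#' @export
writeExpression <- function(M, path, idColumn = "sample_id") {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(M)), collapse = "\t"), con)
  body <- apply(M, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Materialize a binary matrix from a two-column edge list
#'
#' Reads a TSV of \code{id_a<TAB>id_b} pairs and places a 1 at every listed
#' pair over the supplied row/column universes.  Edges naming unknown ids are
#' skipped with a message reporting the count.  With \code{symmetric = TRUE}
#' both orientations are set and the diagonal is zeroed, producing a
#' PPI-style matrix.
#'
#' @param path path to the edge-list TSV.
#' @param rowIds,colIds identifier universes defining the matrix.
#' @param symmetric logical; set both (a, b) and (b, a) and zero the
#'   diagonal (requires \code{rowIds} and \code{colIds} to be the same
#'   universe).
#' @return binary matrix \code{length(rowIds)} x \code{length(colIds)}.
#' @export
readEdgeList <- function(path, rowIds, colIds, symmetric = FALSE) {
  if (length(rowIds) == 0 || length(colIds) == 0)
    stop("empty id universe")
  rowIds <- trimws(rowIds)
  colIds <- trimws(colIds)
  M <- matrix(0, length(rowIds), length(colIds),
              dimnames = list(rowIds, colIds))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 2
    a <- trimws(vapply(parts[!bad], `[[`, "", 1L))
    b <- trimws(vapply(parts[!bad], `[[`, "", 2L))
    ri <- match(a, rowIds)
    ci <- match(b, colIds)
    usable <- !is.na(ri) & !is.na(ci)
    if (symmetric) {
      ri2 <- match(b, rowIds)
      ci2 <- match(a, colIds)
      usable2 <- !is.na(ri2) & !is.na(ci2)
      keep <- usable | usable2
      skipped <- sum(!keep) + sum(bad)
      if (any(usable)) M[cbind(ri[usable], ci[usable])] <- 1
      if (any(usable2)) M[cbind(ri2[usable2], ci2[usable2])] <- 1
    } else {
      skipped <- sum(!usable) + sum(bad)
      if (any(usable)) M[cbind(ri[usable], ci[usable])] <- 1
    }
    if (skipped > 0)
      message(skipped, " edge(s) with unknown ids skipped in '", path, "'")
  }
  if (symmetric) {
    M <- pmax(M, t(M))
    diag(M) <- 0
  }
  if (sum(M) == 0)
    warning("no usable edges in '", path, "'; matrix is all zero")
  M
}

#' Write a binary matrix as a two-column edge list
#'
#' @param M binary matrix with dimnames.
#' @param path output path.
#' @param symmetric logical; write each undirected edge once (upper
#'   triangle).
#' @export
writeEdgeList <- function(M, path, symmetric = FALSE) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  idx <- which(M != 0, arr.ind = TRUE)
  if (symmetric) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  lines <- paste(rownames(M)[idx[, 1]], colnames(M)[idx[, 2]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a signed edge list (ground-truth interactions)
#'
#' Three columns: miRNA id, gene id, sign (-1 or 1).
#'
#' @param G signed matrix in \{-1, 0, 1\} with dimnames.
#' @param path output path.
#' @export
writeSignedEdgeList <- function(G, path) {
  stopifnot(is.matrix(G), !is.null(rownames(G)), !is.null(colnames(G)))
  idx <- which(G != 0, arr.ind = TRUE)
  lines <- paste(rownames(G)[idx[, 1]], colnames(G)[idx[, 2]],
                 G[idx], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed edge list into a \{-1, 0, 1\} matrix
#'
#' @param path path to a three-column TSV (miRNA, gene, sign).
#' @param rowIds,colIds identifier universes.
#' @return signed matrix over the universes.
#' @export
readSignedEdgeList <- function(path, rowIds, colIds) {
  M <- matrix(0, length(rowIds), length(colIds),
              dimnames = list(trimws(rowIds), trimws(colIds)))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(M)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("signed edge list needs three columns: id_a, id_b, sign")
  a <- trimws(vapply(parts, `[[`, "", 1L))
  b <- trimws(vapply(parts, `[[`, "", 2L))
  s <- as.numeric(vapply(parts, `[[`, "", 3L))
  ri <- match(a, rownames(M))
  ci <- match(b, colnames(M))
  ok <- !is.na(ri) & !is.na(ci)
  if (any(!ok))
    message(sum(!ok), " signed edge(s) with unknown ids skipped")
  M[cbind(ri[ok], ci[ok])] <- s[ok]
  M
}

#' Write a membership matrix in long format
#'
#' Columns: module index (1-based), member id, membership value.
#'
#' @param M membership matrix with row names; only entries above
#'   \code{minValue} are written.
#' @param path output path.
#' @param minValue smallest membership value retained.
#' @export
writeMembership <- function(M, path, minValue = 0) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  idx <- which(M > minValue, arr.ind = TRUE)
  lines <- c("module\tmember\tvalue",
             paste(idx[, 2], rownames(M)[idx[, 1]],
                   format(M[idx], digits = 15, trim = TRUE), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format membership matrix
#'
#' @param path path written by \code{\link{writeMembership}}.
#' @param ids row universe (member ids).
#' @param K number of modules (columns).
#' @return numeric matrix \code{length(ids)} x \code{K}.
#' @export
readMembership <- function(path, ids, K) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  M <- matrix(0, length(ids), K, dimnames = list(trimws(ids), NULL))
  if (nrow(df)) {
    ri <- match(trimws(df$member), rownames(M))
    ok <- !is.na(ri) & df$module >= 1 & df$module <= K
    M[cbind(ri[ok], df$module[ok])] <- df$value[ok]
  }
  M
}
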