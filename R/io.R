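## Tabular readers/writers for the formats the tool touches. All files are
## UTF-8 TSV; lines starting '#' are comments, except '#!' directive lines in
## association tables (see readAssociationTable).

.readLinesClean <- function(source) {
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  data.frame(line = seq_along(lines), text = lines,
             stringsAsFactors = FALSE)
}

.normId <- function(x) tolower(trimws(x))

#' Read a miRNA-disease association table
#'
#' Each data row names one (miRNA, disease) pair; the binary association
#' matrix gets a 1 wherever a pair appears at least once. Identifier order is
#' first-appearance order. Identifiers are matched case-insensitively after
#' trimming whitespace (the first-seen spelling is kept); duplicate pairs
#' collapse silently to a single 1 with a reported count.
#'
#' Dialect: tab-separated columns, \code{'#'} starts a comment line, and
#' optional directive lines \code{"#!mirna<TAB>id"} / \code{"#!disease<TAB>id"}
#' pre-register identifiers in order, which allows round-tripping datasets
#' containing miRNAs or diseases without any association.
#'
#' @param source file path or connection.
#' @param mirnaCol,diseaseCol 1-based column indices of the two identifiers.
#' @return An [AssociationDataset-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("m1\td1", "m2\td2", "m1\td1"), tf)
#' readAssociationTable(tf)
#' @export
readAssociationTable <- function(source, mirnaCol = 1L, diseaseCol = 2L) {
  df <- .readLinesClean(source)
  mKeys <- character(); mNames <- character()
  dKeys <- character(); dNames <- character()
  register <- function(keys, names, id) {
    k <- .normId(id)
    if (!(k %in% keys)) {
      keys <- c(keys, k); names <- c(names, trimws(id))
    }
    list(keys = keys, names = names)
  }
  pairs_m <- character(); pairs_d <- character()
  need <- max(mirnaCol, diseaseCol)
  for (r in seq_len(nrow(df))) {
    txt <- df$text[r]
    if (!nzchar(trimws(txt))) next
    if (startsWith(txt, "#!")) {
      f <- strsplit(sub("^#!", "", txt), "\t", fixed = TRUE)[[1L]]
      if (length(f) != 2L)
        stop(sprintf("malformed directive at line %d", df$line[r]))
      if (f[1L] == "mirna") {
        reg <- register(mKeys, mNames, f[2L]); mKeys <- reg$keys; mNames <- reg$names
      } else if (f[1L] == "disease") {
        reg <- register(dKeys, dNames, f[2L]); dKeys <- reg$keys; dNames <- reg$names
      } else stop(sprintf("unknown directive '%s' at line %d", f[1L], df$line[r]))
      next
    }
    if (startsWith(txt, "#")) next
    f <- strsplit(txt, "\t", fixed = TRUE)[[1L]]
    if (length(f) < need)
      stop(sprintf("malformed row at line %d: expected >= %d columns, got %d",
                   df$line[r], need, length(f)))
    mi <- f[mirnaCol]; di <- f[diseaseCol]
    if (!nzchar(trimws(mi)) || !nzchar(trimws(di)))
      stop(sprintf("empty identifier at line %d", df$line[r]))
    reg <- register(mKeys, mNames, mi); mKeys <- reg$keys; mNames <- reg$names
    reg <- register(dKeys, dNames, di); dKeys <- reg$keys; dNames <- reg$names
    pairs_m <- c(pairs_m, .normId(mi)); pairs_d <- c(pairs_d, .normId(di))
  }
  if (!length(pairs_m)) stop("no association rows found in input")
  A <- matrix(0, length(mKeys), length(dKeys))
  i <- match(pairs_m, mKeys); j <- match(pairs_d, dKeys)
  dup <- duplicated(cbind(i, j))
  if (any(dup))
    message(sprintf("collapsed %d duplicate association row(s)", sum(dup)))
  A[cbind(i, j)] <- 1
  AssociationDataset(A, mirnaIds = mNames, diseaseIds = dNames)
}

#' Write an association table
#'
#' Emits identifier directives (preserving order and empty rows/columns)
#' followed by one row per known association, so that
#' \code{readAssociationTable(writeAssociationTable(x, f))} reproduces the
#' matrix and both identifier orders exactly.
#'
#' @param dataset an [AssociationDataset-class].
#' @param sink file path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeAssociationTable <- function(dataset, sink) {
  stopifnot(is(dataset, "AssociationDataset"))
  out <- c(
    paste0("#!mirna\t", dataset@mirnaIds),
    paste0("#!disease\t", dataset@diseaseIds)
  )
  idx <- which(dataset@assoc == 1, arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    out <- c(out, paste(dataset@mirnaIds[idx[, 1L]],
                        dataset@diseaseIds[idx[, 2L]], sep = "\t"))
  }
  writeLines(out, sink)
  invisible(sink)
}

#' Read a square similarity matrix
#'
#' Expects a header row of identifiers (with or without a leading empty
#' cell) and rows of the form \code{id<TAB>values...}. Row and column
#' identifiers must agree (case-insensitively, after trimming). Asymmetry up
#' to 1e-6 is averaged away; larger asymmetry is an error.
#'
#' @param source file path or connection.
#' @param name label for the returned kernel.
#' @return A [SimilarityKernel-class].
#' @export
readSimilarityMatrix <- function(source, name = "kernel") {
  df <- .readLinesClean(source)
  keep <- nzchar(trimws(df$text)) & !startsWith(df$text, "#")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) stop("similarity matrix input has no data rows")
  header <- strsplit(df$text[1L], "\t", fixed = TRUE)[[1L]]
  if (!nzchar(trimws(header[1L]))) header <- header[-1L]
  colIds <- trimws(header)
  n <- length(colIds)
  body <- matrix(NA_real_, n, n)
  rowIds <- character(n)
  if (nrow(df) - 1L != n)
    stop(sprintf("non-square similarity matrix: %d columns but %d data rows",
                 n, nrow(df) - 1L))
  for (r in seq_len(n)) {
    f <- strsplit(df$text[r + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 1L)
      stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                   df$line[r + 1L], n + 1L, length(f)))
    rowIds[r] <- trimws(f[1L])
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(vals))
      stop(sprintf("non-numeric matrix entry at line %d", df$line[r + 1L]))
    body[r, ] <- vals
  }
  if (!identical(.normId(rowIds), .normId(colIds)))
    stop("row and column identifiers of the similarity matrix differ")
  asym <- max(abs(body - t(body)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix asymmetry %.3g exceeds 1e-6", asym))
  body <- (body + t(body)) / 2
  SimilarityKernel(body, ids = colIds, name = name)
}

#' Write a similarity matrix
#'
#' @param kernel a [SimilarityKernel-class].
#' @param sink file path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeSimilarityMatrix <- function(kernel, sink) {
  stopifnot(is(kernel, "SimilarityKernel"))
  ids <- kernel@ids
  rows <- vapply(seq_along(ids), function(r) {
    paste(c(ids[r], format(kernel@matrix[r, ], digits = 17, trim = TRUE,
                           scientific = FALSE)), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(c("", ids), collapse = "\t"), rows), sink)
  invisible(sink)
}

#' Read disease DAG edge lists
#'
#' Rows are \code{(disease_id, child_term, parent_term)} triples; a row with
#' an empty parent field declares a root term. Per disease, the term set is
#' the union of all mentioned terms and the edge set points from parent to
#' child. Term document frequencies are recomputed from the collection.
#'
#' @param source file path or connection.
#' @return A [DAGCollection-class]. A cycle inside any disease's DAG is an
#'   error naming the disease.
#' @export
readDagEdges <- function(source) {
  df <- .readLinesClean(source)
  keep <- nzchar(trimws(df$text)) & !startsWith(df$text, "#")
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no DAG rows found in input")
  terms <- list(); edges <- list(); order <- character()
  for (r in seq_len(nrow(df))) {
    f <- strsplit(df$text[r], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || length(f) > 3L)
      stop(sprintf("malformed DAG row at line %d: expected 2-3 columns",
                   df$line[r]))
    dis <- trimws(f[1L]); child <- trimws(f[2L])
    parent <- if (length(f) >= 3L) trimws(f[3L]) else ""
    if (!nzchar(dis) || !nzchar(child))
      stop(sprintf("empty identifier at line %d", df$line[r]))
    if (!(dis %in% order)) {
      order <- c(order, dis); terms[[dis]] <- character()
      edges[[dis]] <- matrix(character(), 0L, 2L)
    }
    terms[[dis]] <- union(terms[[dis]], child)
    if (nzchar(parent)) {
      terms[[dis]] <- union(terms[[dis]], parent)
      edges[[dis]] <- rbind(edges[[dis]], c(parent, child))
    }
  }
  dags <- lapply(order, function(dis) {
    e <- unique(edges[[dis]])
    if (!.dagIsAcyclic(union(terms[[dis]], dis), e))
      stop(sprintf("cycle detected in DAG of disease '%s'", dis))
    DiseaseDAG(dis, terms = terms[[dis]], edges = e)
  })
  DAGCollection(dags)
}

#' Write disease DAG edge lists
#'
#' Inverse of [readDagEdges()]: one row per edge as
#' \code{(disease, child, parent)}; a root-only DAG is emitted as a single
#' row with empty parent.
#'
#' @param collection a [DAGCollection-class].
#' @param sink file path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeDagEdges <- function(collection, sink) {
  stopifnot(is(collection, "DAGCollection"))
  out <- unlist(lapply(collection@dags, function(d) {
    if (nrow(d@edges) == 0L)
      return(paste(d@diseaseId, d@diseaseId, "", sep = "\t"))
    paste(d@diseaseId, d@edges[, 2L], d@edges[, 1L], sep = "\t")
  }), use.names = FALSE)
  writeLines(out, sink)
  invisible(sink)
}

#' Write a ranked prediction table
#'
#' Emits one TSV row \code{(disease_id, rank, mirna_id, score, known_flag)}
#' per miRNA and disease. Ranks are computed per disease over the candidate
#' miRNAs only (those without a known association, \code{known_flag = 0}),
#' in descending score order with ties broken by miRNA identifier; known
#' associations are listed after the candidates with rank \code{NA}.
#'
#' @param scores numeric matrix aligned to \code{dataset} (rows = miRNAs).
#' @param dataset the [AssociationDataset-class] providing identifiers and
#'   known flags.
#' @param sink file path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writePredictionTable <- function(scores, dataset, sink) {
  stopifnot(is(dataset, "AssociationDataset"))
  if (!identical(dim(scores), dim(dataset@assoc)))
    stop("score matrix shape does not match the dataset")
  out <- c("disease_id\trank\tmirna_id\tscore\tknown_flag")
  for (j in seq_along(dataset@diseaseIds)) {
    known <- dataset@assoc[, j] == 1
    cand <- which(!known)
    ord <- cand[order(-scores[cand, j], dataset@mirnaIds[cand])]
    if (length(ord))
      out <- c(out, sprintf("%s\t%d\t%s\t%.10g\t0", dataset@diseaseIds[j],
                            seq_along(ord), dataset@mirnaIds[ord],
                            scores[ord, j]))
    kn <- which(known)
    kn <- kn[order(dataset@mirnaIds[kn])]
    if (length(kn))
      out <- c(out, sprintf("%s\tNA\t%s\t%.10g\t1", dataset@diseaseIds[j],
                            dataset@mirnaIds[kn], scores[kn, j]))
  }
  writeLines(out, sink)
  invisible(sink)
}
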