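## Base kernel constructions: DAG-based disease semantic similarity (two
## contribution models), Gaussian interaction-profile kernels for both sides,
## integration of a partial miRNA functional similarity matrix, and PSD
## repair with cosine normalization.

.childrenOf <- function(dag, term) {
  if (nrow(dag@edges) == 0L) return(character())
  dag@edges[dag@edges[, 1L] == term, 2L]
}

#' Model-1 semantic contributions of a disease DAG
#'
#' The disease itself contributes 1; any ancestor term contributes
#' \code{delta} times the largest contribution among its children in the
#' DAG, so terms in the same layer contribute equally and contributions
#' decay geometrically with distance from the disease.
#'
#' @param dag a [DiseaseDAG-class].
#' @param delta semantic contribution factor in (0, 1]; default 0.5,
#'   following the established disease-similarity convention.
#' @return A [ContributionMap-class] with model = 1.
#' @examples
#' dag <- DiseaseDAG("d1", terms = c("d1", "P"),
#'                   edges = rbind(c("P", "d1")))
#' semanticContributionsModel1(dag, delta = 0.5)@contributions
#' @export
semanticContributionsModel1 <- function(dag, delta = 0.5) {
  stopifnot(is(dag, "DiseaseDAG"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("delta must be a single value in (0, 1]")
  contrib <- stats::setNames(rep(NA_real_, length(dag@terms)), dag@terms)
  contrib[dag@diseaseId] <- 1
  visit <- function(t, stack = character()) {
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    ch <- .childrenOf(dag, t)
    if (!length(ch))
      stop(sprintf("term '%s' has no descendant path to disease '%s'",
                   t, dag@diseaseId))
    v <- delta * max(vapply(ch, visit, numeric(1L)))
    contrib[[t]] <<- v
    v
  }
  for (t in dag@terms) visit(t)
  new("ContributionMap", diseaseId = dag@diseaseId, contributions = contrib,
      model = 1L, delta = delta)
}

#' Semantic value of a contribution map
#'
#' The sum of all per-term contributions (the DV of the disease under the
#' map's model).
#'
#' @param contribs a [ContributionMap-class].
#' @return A single numeric value.
#' @export
semanticValue <- function(contribs) {
  stopifnot(is(contribs, "ContributionMap"))
  sum(contribs@contributions)
}

.semanticKernelFromContribs <- function(contribMaps, warnZero = FALSE) {
  ids <- names(contribMaps)
  n <- length(ids)
  dv <- vapply(contribMaps, function(cm) sum(cm@contributions), numeric(1L))
  K <- diag(1, n)
  zeroDiag <- dv <= 0
  if (any(zeroDiag) && warnZero)
    warning(sprintf(
      "disease(s) %s have zero semantic value; diagonal set to 1 by convention",
      paste(ids[zeroDiag], collapse = ", ")))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      ci <- contribMaps[[i]]@contributions
      for (j in seq(i + 1L, n)) {
        cj <- contribMaps[[j]]@contributions
        shared <- intersect(names(ci), names(cj))
        denom <- dv[i] + dv[j]
        val <- if (length(shared) && denom > 0)
          sum(ci[shared] + cj[shared]) / denom else 0
        K[i, j] <- K[j, i] <- val
      }
    }
  }
  dimnames(K) <- list(ids, ids)
  K
}

#' Model-1 disease semantic similarity kernel
#'
#' Similarity of two diseases is the sum, over the shared terms of their
#' DAGs, of both diseases' model-1 contributions, normalized by the sum of
#' their semantic values; diseases with a larger common DAG part score
#' higher. The diagonal is exactly 1.
#'
#' @param collection a [DAGCollection-class] with one DAG per disease.
#' @param delta semantic contribution factor; see
#'   [semanticContributionsModel1()].
#' @param diseaseIds optional subset/order of diseases; defaults to all
#'   diseases in the collection. A requested disease without a DAG is an
#'   error.
#' @return A [SimilarityKernel-class] named "SS1".
#' @export
semanticSimilarityModel1 <- function(collection, delta = 0.5,
                                     diseaseIds = NULL) {
  stopifnot(is(collection, "DAGCollection"))
  if (is.null(diseaseIds)) diseaseIds <- names(collection@dags)
  missing <- setdiff(diseaseIds, names(collection@dags))
  if (length(missing))
    stop(sprintf("no DAG for disease(s): %s", paste(missing, collapse = ", ")))
  maps <- lapply(collection@dags[diseaseIds], semanticContributionsModel1,
                 delta = delta)
  SimilarityKernel(.semanticKernelFromContribs(maps), ids = diseaseIds,
                   name = "SS1", metadata = list(delta = delta))
}

#' Model-2 semantic contributions (document-frequency weighted)
#'
#' A term appearing in fewer disease DAGs is considered more specific and
#' contributes more: its contribution is \code{-log(DAGt / nd)} with the
#' natural logarithm, where \code{DAGt} is the number of DAGs containing the
#' term and \code{nd} the number of diseases in the collection. The
#' contribution of a term is identical across all diseases containing it.
#'
#' @param collection a [DAGCollection-class].
#' @return Named list of [ContributionMap-class] objects (model = 2), one
#'   per disease.
#' @export
semanticContributionsModel2 <- function(collection) {
  stopifnot(is(collection, "DAGCollection"))
  nd <- length(collection@dags)
  tf <- collection@termFrequency
  if (any(tf < 1L) || any(tf > nd))
    stop("term frequencies must lie in [1, number of diseases]")
  d2 <- -log(tf / nd)
  lapply(collection@dags, function(dag) {
    new("ContributionMap", diseaseId = dag@diseaseId,
        contributions = d2[dag@terms], model = 2L, delta = NA_real_)
  })
}

#' Model-2 disease semantic similarity kernel
#'
#' As the model-1 kernel but with document-frequency contributions; the
#' per-disease semantic value is the sum of its model-2 contributions. A
#' disease whose every term is ubiquitous has semantic value 0; its diagonal
#' entry is set to 1 by convention with a warning.
#'
#' @inheritParams semanticSimilarityModel1
#' @return A [SimilarityKernel-class] named "SS2".
#' @export
semanticSimilarityModel2 <- function(collection, diseaseIds = NULL) {
  stopifnot(is(collection, "DAGCollection"))
  if (is.null(diseaseIds)) diseaseIds <- names(collection@dags)
  missing <- setdiff(diseaseIds, names(collection@dags))
  if (length(missing))
    stop(sprintf("no DAG for disease(s): %s", paste(missing, collapse = ", ")))
  maps <- semanticContributionsModel2(collection)[diseaseIds]
  SimilarityKernel(.semanticKernelFromContribs(maps, warnZero = TRUE),
                   ids = diseaseIds, name = "SS2")
}

#' Gaussian bandwidth of an interaction-profile kernel
#'
#' The effective bandwidth is the unnormalized bandwidth divided by the mean
#' squared norm of the interaction profiles on the requested side (i.e. by
#' the average number of known associations per disease or per miRNA, since
#' profiles are binary).
#'
#' @param dataset an [AssociationDataset-class].
#' @param axis "disease" (profiles are columns of the association matrix) or
#'   "mirna" (rows).
#' @param gammaRaw unnormalized bandwidth, > 0; default 1.
#' @return A [GaussianBandwidth-class].
#' @export
gaussianBandwidth <- function(dataset, axis = c("disease", "mirna"),
                              gammaRaw = 1) {
  axis <- match.arg(axis)
  if (gammaRaw <= 0) stop("gammaRaw must be positive")
  A <- assocMatrix(dataset)
  if (sum(A) == 0)
    stop("association matrix has no known associations; bandwidth undefined")
  P <- if (axis == "disease") t(A) else A
  meanSq <- mean(rowSums(P^2))
  new("GaussianBandwidth", gammaRaw = gammaRaw, gamma = gammaRaw / meanSq)
}

#' Gaussian interaction-profile kernel
#'
#' Radial-basis similarity between binary interaction profiles: the profile
#' of a disease is its column of the association matrix, that of a miRNA its
#' row. \code{K(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)} with the
#' normalized bandwidth of [gaussianBandwidth()]. The kernel is positive
#' semidefinite with unit diagonal by construction. Entities with an all-zero
#' profile (new diseases/miRNAs) are allowed; only an entirely empty
#' association matrix is an error.
#'
#' @inheritParams gaussianBandwidth
#' @return A [SimilarityKernel-class] named "GD" (disease axis) or "GM"
#'   (miRNA axis); the bandwidth is recorded in the kernel metadata.
#' @examples
#' ds <- AssociationDataset(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' kernelMatrix(gaussianProfileKernel(ds, "disease"))[1, 2]  # exp(-1)
#' @export
gaussianProfileKernel <- function(dataset, axis = c("disease", "mirna"),
                                  gammaRaw = 1) {
  axis <- match.arg(axis)
  bw <- gaussianBandwidth(dataset, axis, gammaRaw)
  A <- assocMatrix(dataset)
  P <- if (axis == "disease") t(A) else A
  ids <- if (axis == "disease") diseaseIds(dataset) else mirnaIds(dataset)
  G <- tcrossprod(P)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  K <- exp(-bw@gamma * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  SimilarityKernel(K, ids = ids, name = if (axis == "disease") "GD" else "GM",
                   metadata = list(bandwidth = bw))
}

#' Integrate a partial functional similarity matrix with a Gaussian kernel
#'
#' Produces a full miRNA similarity kernel over all miRNAs: where both
#' miRNAs are covered by the (possibly partial) functional similarity
#' matrix, its value is used; everywhere else the Gaussian
#' interaction-profile value fills in.
#'
#' @param fs [SimilarityKernel-class] over a subset of the miRNAs.
#' @param gm [SimilarityKernel-class] over all miRNAs (the fill-in kernel).
#' @return A [SimilarityKernel-class] over \code{kernelIds(gm)} named
#'   "FSint". An fs identifier absent from gm is an error.
#' @export
integrateMirnaSimilarity <- function(fs, gm) {
  stopifnot(is(fs, "SimilarityKernel"), is(gm, "SimilarityKernel"))
  pos <- match(.normId(fs@ids), .normId(gm@ids))
  if (anyNA(pos))
    stop(sprintf("functional-similarity id(s) absent from the full kernel: %s",
                 paste(fs@ids[is.na(pos)], collapse = ", ")))
  K <- gm@matrix
  K[pos, pos] <- fs@matrix
  K <- (K + t(K)) / 2
  diag(K) <- 1
  SimilarityKernel(K, ids = gm@ids, name = "FSint",
                   metadata = list(covered = gm@ids[pos]))
}

#' Repair a kernel to positive semidefiniteness
#'
#' The eigendecomposition solver requires nonnegative eigenvalue products,
#' but semantic and functional similarity matrices are not guaranteed PSD.
#' \code{clip} sets negative eigenvalues to zero and reassembles;
#' \code{shift} adds \code{(|lambda_min| + 1e-8) * I} when the smallest
#' eigenvalue is negative. Either repair is followed by cosine normalization
#' \code{K(i,j) / sqrt(K(i,i) K(j,j))} restoring a unit diagonal.
#' \code{none} passes the input through untouched. The smallest eigenvalue
#' before repair is recorded in the metadata as \code{lambdaMinBefore}.
#'
#' @param k a symmetric [SimilarityKernel-class].
#' @param mode "clip" (default), "shift" or "none".
#' @return A repaired [SimilarityKernel-class]. A zero diagonal entry after
#'   repair is an error (the entity carries no similarity mass at all).
#' @export
repairKernel <- function(k, mode = c("clip", "shift", "none")) {
  mode <- match.arg(mode)
  stopifnot(is(k, "SimilarityKernel"))
  if (mode == "none") return(k)
  e <- eigen(k@matrix, symmetric = TRUE)
  lamMin <- min(e$values)
  if (mode == "clip") {
    vals <- pmax(e$values, 0)
    M <- e$vectors %*% (vals * t(e$vectors))
  } else {
    M <- k@matrix
    if (lamMin < 0) M <- M + diag(abs(lamMin) + 1e-8, nrow(M))
  }
  d <- diag(M)
  if (any(d <= 0))
    stop("zero diagonal entry after repair; kernel cannot be normalized")
  s <- 1 / sqrt(d)
  M <- M * tcrossprod(s)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  meta <- k@metadata
  meta$lambdaMinBefore <- lamMin
  meta$repairMode <- mode
  SimilarityKernel(M, ids = k@ids, name = k@name, metadata = meta)
}
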