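#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' Bipartite association dataset
#'
#' Holds the binary association matrix between miRNAs (rows) and diseases
#' (columns) together with the ordered identifier lists of both sides. The
#' orientation is fixed package-wide: rows are miRNAs, columns are diseases,
#' so a column of the matrix is a disease interaction profile and a row is a
#' miRNA interaction profile.
#'
#' @slot mirnaIds character vector of unique miRNA identifiers (row order).
#' @slot diseaseIds character vector of unique disease identifiers (column
#'   order).
#' @slot assoc numeric matrix of 0/1 entries, dimension
#'   \code{length(mirnaIds) x length(diseaseIds)}.
#'
#' @seealso [AssociationDataset()], [readAssociationTable()]
#' @export
setClass("AssociationDataset",
  representation(
    mirnaIds = "character",
    diseaseIds = "character",
    assoc = "matrix"
  )
)

setValidity("AssociationDataset", function(object) {
  msgs <- character()
  A <- object@assoc
  if (!is.numeric(A)) msgs <- c(msgs, "association matrix must be numeric")
  if (length(object@mirnaIds) < 1L || length(object@diseaseIds) < 1L)
    msgs <- c(msgs, "need at least one miRNA and one disease")
  if (anyDuplicated(object@mirnaIds))
    msgs <- c(msgs, "duplicated miRNA identifiers")
  if (anyDuplicated(object@diseaseIds))
    msgs <- c(msgs, "duplicated disease identifiers")
  if (nrow(A) != length(object@mirnaIds) ||
      ncol(A) != length(object@diseaseIds))
    msgs <- c(msgs, "matrix dimensions do not match identifier lists")
  if (is.numeric(A) && length(A) && !all(A %in% c(0, 1)))
    msgs <- c(msgs, "association matrix entries must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationDataset
#'
#' @param assoc binary matrix, rows = miRNAs, columns = diseases. Dimnames,
#'   when present, are used as identifiers unless overridden.
#' @param mirnaIds,diseaseIds identifier vectors; default to the dimnames of
#'   \code{assoc}.
#' @return An [AssociationDataset-class] object.
#' @examples
#' ds <- AssociationDataset(matrix(c(1, 0, 0, 1), 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' nMirnas(ds)
#' @export
AssociationDataset <- function(assoc,
                               mirnaIds = rownames(assoc),
                               diseaseIds = colnames(assoc)) {
  if (is.null(mirnaIds)) mirnaIds <- paste0("m", seq_len(nrow(assoc)))
  if (is.null(diseaseIds)) diseaseIds <- paste0("d", seq_len(ncol(assoc)))
  assoc <- as.matrix(assoc)
  storage.mode(assoc) <- "double"
  dimnames(assoc) <- list(mirnaIds, diseaseIds)
  new("AssociationDataset", mirnaIds = as.character(mirnaIds),
      diseaseIds = as.character(diseaseIds), assoc = assoc)
}

#' Labeled square similarity kernel
#'
#' A symmetric similarity matrix over one side of the bipartite problem
#' (either diseases or miRNAs), aligned to an ordered identifier list.
#' Validity tolerates asymmetry up to 1e-10 (the readers symmetrize noisier
#' input themselves). Unit diagonal is enforced only by [repairKernel()], not
#' here, because raw semantic or functional matrices may arrive unnormalized.
#'
#' @slot ids character vector of identifiers (row/column order).
#' @slot matrix numeric square matrix aligned to \code{ids}.
#' @slot name free-text label, e.g. "SS1" or "GD".
#' @slot metadata list of construction details (bandwidths, repair reports).
#' @export
setClass("SimilarityKernel",
  representation(
    ids = "character",
    matrix = "matrix",
    name = "character",
    metadata = "list"
  ),
  prototype(name = "kernel", metadata = list())
)

setValidity("SimilarityKernel", function(object) {
  msgs <- character()
  M <- object@matrix
  if (nrow(M) != ncol(M)) msgs <- c(msgs, "kernel matrix must be square")
  if (nrow(M) != length(object@ids))
    msgs <- c(msgs, "kernel dimension does not match identifier list")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicated identifiers")
  if (length(M) && !all(is.finite(M)))
    msgs <- c(msgs, "kernel entries must be finite")
  if (length(M) && max(abs(M - t(M))) > 1e-10)
    msgs <- c(msgs, "kernel matrix is not symmetric (tolerance 1e-10)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityKernel
#'
#' @param matrix square symmetric numeric matrix.
#' @param ids identifiers; default rownames of \code{matrix}.
#' @param name label for the kernel.
#' @param metadata optional list of construction details.
#' @return A [SimilarityKernel-class] object.
#' @export
SimilarityKernel <- function(matrix, ids = rownames(matrix), name = "kernel",
                             metadata = list()) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(ids, ids)
  new("SimilarityKernel", ids = as.character(ids), matrix = matrix,
      name = name, metadata = metadata)
}

#' Ancestor DAG of one disease term
#'
#' The MeSH-descriptor style directed acyclic graph of a disease: the term
#' itself plus all its ancestors, with edges pointing from parent to child.
#' A disease listed under several tree positions is represented by the union
#' of all its ancestor paths in a single DAG.
#'
#' @slot diseaseId identifier of the disease the DAG describes.
#' @slot terms character vector of term identifiers, including the disease.
#' @slot edges character matrix with columns \code{parent}, \code{child};
#'   zero rows for a root-only DAG.
#' @export
setClass("DiseaseDAG",
  representation(
    diseaseId = "character",
    terms = "character",
    edges = "matrix"
  )
)

.dagIsAcyclic <- function(terms, edges) {
  ## Kahn's algorithm on parent -> child edges
  if (nrow(edges) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(terms)), terms)
  for (k in seq_len(nrow(edges))) {
    indeg[edges[k, 2L]] <- indeg[edges[k, 2L]] + 1L
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- edges[edges[, 1L] == t, 2L]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  seen == length(terms)
}

setValidity("DiseaseDAG", function(object) {
  msgs <- character()
  if (length(object@diseaseId) != 1L)
    msgs <- c(msgs, "diseaseId must be a single identifier")
  if (!(object@diseaseId %in% object@terms))
    msgs <- c(msgs, "the disease itself must be a member of its term set")
  if (ncol(object@edges) != 2L)
    msgs <- c(msgs, "edges must have two columns (parent, child)")
  else if (nrow(object@edges) &&
           !all(object@edges %in% object@terms))
    msgs <- c(msgs, "every edge endpoint must be in the term set")
  if (ncol(object@edges) == 2L &&
      !.dagIsAcyclic(object@terms, object@edges))
    msgs <- c(msgs, sprintf("cycle detected in DAG of disease '%s'",
                            object@diseaseId))
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiseaseDAG
#'
#' @param diseaseId disease identifier.
#' @param terms term identifiers (the disease is added if absent).
#' @param edges two-column character matrix (parent, child), or NULL.
#' @return A [DiseaseDAG-class] object.
#' @export
DiseaseDAG <- function(diseaseId, terms = diseaseId, edges = NULL) {
  terms <- unique(c(as.character(terms), diseaseId))
  if (is.null(edges)) {
    edges <- matrix(character(), 0L, 2L)
  } else {
    edges <- matrix(as.character(edges), ncol = 2L,
                    dimnames = NULL)
    edges <- unique(edges)
  }
  colnames(edges) <- c("parent", "child")
  new("DiseaseDAG", diseaseId = diseaseId, terms = terms, edges = edges)
}

#' Collection of disease DAGs with term document frequencies
#'
#' @slot dags named list of [DiseaseDAG-class] objects (names = disease ids).
#' @slot termFrequency named integer vector: for each term, the number of
#'   DAGs in the collection whose term set contains it.
#' @export
setClass("DAGCollection",
  representation(
    dags = "list",
    termFrequency = "integer"
  )
)

.countTermFrequency <- function(dags) {
  tab <- table(unlist(lapply(dags, function(d) unique(d@terms)),
                      use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

setValidity("DAGCollection", function(object) {
  msgs <- character()
  if (!all(vapply(object@dags, is, logical(1L), "DiseaseDAG")))
    msgs <- c(msgs, "all elements of dags must be DiseaseDAG objects")
  else {
    ids <- vapply(object@dags, function(d) d@diseaseId, character(1L))
    if (!identical(unname(names(object@dags)), unname(ids)))
      msgs <- c(msgs, "list names must equal the contained disease ids")
    tf <- .countTermFrequency(object@dags)
    stored <- object@termFrequency[names(tf)]
    if (length(tf) != length(object@termFrequency) ||
        any(is.na(stored)) || !all(stored == tf))
      msgs <- c(msgs, "termFrequency inconsistent with DAG membership")
    if (length(object@termFrequency) &&
        (min(object@termFrequency) < 1L ||
         max(object@termFrequency) > length(object@dags)))
      msgs <- c(msgs, "term frequencies must lie in [1, number of diseases]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DAGCollection
#'
#' Term frequencies are recomputed from the DAG membership, never supplied.
#'
#' @param dags list of [DiseaseDAG-class] objects.
#' @return A [DAGCollection-class] object.
#' @export
DAGCollection <- function(dags) {
  names(dags) <- vapply(dags, function(d) d@diseaseId, character(1L))
  new("DAGCollection", dags = dags, termFrequency = .countTermFrequency(dags))
}

## ---------------------------------------------------------------------------
## Model-side value objects
## ---------------------------------------------------------------------------

#' Per-term semantic contribution map of one disease
#'
#' @slot diseaseId disease the map belongs to.
#' @slot contributions named numeric vector over the disease's term set.
#' @slot model integer 1 or 2 (which contribution model produced it).
#' @slot delta semantic contribution factor (model 1 only; NA for model 2).
#' @export
setClass("ContributionMap",
  representation(
    diseaseId = "character",
    contributions = "numeric",
    model = "integer",
    delta = "numeric"
  )
)

setValidity("ContributionMap", function(object) {
  msgs <- character()
  v <- object@contributions
  if (!length(v)) msgs <- c(msgs, "contribution map must be non-empty")
  if (!(object@model %in% c(1L, 2L))) msgs <- c(msgs, "model must be 1 or 2")
  if (object@model == 1L) {
    if (!isTRUE(all.equal(unname(v[object@diseaseId]), 1)))
      msgs <- c(msgs, "model-1 contribution of the disease itself must be 1")
    if (length(v) && (min(v) <= 0 || max(v) > 1 + 1e-12))
      msgs <- c(msgs, "model-1 contributions must lie in (0, 1]")
  } else if (length(v) && min(v) < 0) {
    msgs <- c(msgs, "model-2 contributions must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gaussian interaction-profile kernel bandwidth
#'
#' @slot gammaRaw unnormalized bandwidth (dimensionless, the gamma-prime of
#'   the kernel definition).
#' @slot gamma effective bandwidth after division by the mean squared
#'   interaction-profile norm.
#' @export
setClass("GaussianBandwidth",
  representation(gammaRaw = "numeric", gamma = "numeric")
)

setValidity("GaussianBandwidth", function(object) {
  if (object@gammaRaw <= 0) return("gammaRaw must be positive")
  if (!is.finite(object@gamma) || object@gamma <= 0)
    return("gamma must be positive and finite")
  TRUE
})

#' Symmetric eigendecomposition of a kernel
#'
#' @slot vectors matrix of orthonormal eigenvector columns.
#' @slot values eigenvalues in ascending order, aligned to the columns.
#' @export
setClass("EigenFactorization",
  representation(vectors = "matrix", values = "numeric")
)

setValidity("EigenFactorization", function(object) {
  Q <- object@vectors
  if (ncol(Q) != length(object@values))
    return("eigenvalue list must align to eigenvector columns")
  if (max(abs(crossprod(Q) - diag(ncol(Q)))) > 1e-8)
    return("eigenvector columns must be orthonormal (tolerance 1e-8)")
  if (is.unsorted(object@values)) return("eigenvalues must be ascending")
  TRUE
})

#' Kronecker RLS fit
#'
#' Solution of the regularized least squares system whose pairwise kernel is
#' the Kronecker product of a disease kernel and a miRNA kernel, stored in
#' factored form: the predicted score matrix is \code{Qm C t(Qd)} and the
#' dual coefficients alpha (matrix form, rows = miRNAs) satisfy
#' \code{(K + lambda I) vec(alpha) = vec(Y)} with \code{K = Kd \%x\% Km}.
#'
#' @slot lam regularization parameter (>= 0).
#' @slot Cmat intermediate coefficient matrix C in the eigenbasis, nm x nd.
#' @slot F predicted score matrix, nm x nd.
#' @slot alpha dual coefficient matrix, nm x nd.
#' @slot Qm,Qd eigenvector matrices of the miRNA / disease kernels.
#' @export
setClass("KronRLSFit",
  representation(
    lam = "numeric",
    Cmat = "matrix",
    F = "matrix",
    alpha = "matrix",
    Qm = "matrix",
    Qd = "matrix"
  )
)

setValidity("KronRLSFit", function(object) {
  msgs <- character()
  if (object@lam < 0) msgs <- c(msgs, "lam must be nonnegative")
  if (!all(is.finite(object@F)) || !all(is.finite(object@alpha)))
    msgs <- c(msgs, "fit contains non-finite entries")
  rec <- object@Qm %*% object@Cmat %*% t(object@Qd)
  if (max(abs(rec - object@F)) > 1e-10)
    msgs <- c(msgs, "F is not reproducible from the stored factors")
  if (length(msgs)) msgs else TRUE
})

#' Simplex weight vector over base kernels on one side
#'
#' @slot values nonnegative weights summing to 1.
#' @export
setClass("KernelWeights", representation(values = "numeric"))

setValidity("KernelWeights", function(object) {
  v <- object@values
  if (!length(v)) return("weight vector must be non-empty")
  if (min(v) < 0) return("weights must be nonnegative")
  if (abs(sum(v) - 1) > 1e-10) return("weights must sum to 1 (tolerance 1e-10)")
  TRUE
})

#' @describeIn KernelWeights-class constructor; normalizes nothing, the
#'   caller must supply a simplex vector.
#' @param values nonnegative numeric vector summing to 1.
#' @export
KernelWeights <- function(values) new("KernelWeights", values = values)

#' Configuration of the multiple-kernel optimizer
#'
#' @slot lam selected regularization parameter (used when no grid search is
#'   requested).
#' @slot sigma selected L2 penalty on the kernel weight vectors.
#' @slot lamGrid candidate lambda values for selection.
#' @slot sigmaGrid candidate sigma values for selection.
#' @slot maxOuterIters maximum alternating cycles.
#' @slot relTol relative objective-decrease convergence threshold.
#' @slot seed integer seed for any randomized step.
#' @export
setClass("MKLConfig",
  representation(
    lam = "numeric",
    sigma = "numeric",
    lamGrid = "numeric",
    sigmaGrid = "numeric",
    maxOuterIters = "integer",
    relTol = "numeric",
    seed = "integer"
  )
)

setValidity("MKLConfig", function(object) {
  msgs <- character()
  if (object@lam < 0) msgs <- c(msgs, "lam must be nonnegative")
  if (object@sigma < 0) msgs <- c(msgs, "sigma must be nonnegative")
  if (!length(object@lamGrid) || !length(object@sigmaGrid))
    msgs <- c(msgs, "hyperparameter grids must be non-empty")
  if (any(object@lamGrid <= 0)) msgs <- c(msgs, "lamGrid must be positive")
  if (object@relTol <= 0) msgs <- c(msgs, "relTol must be positive")
  if (object@maxOuterIters < 1L) msgs <- c(msgs, "maxOuterIters must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Create an MKLConfig
#'
#' Defaults: lambda grid \code{2^seq(-15, 30, by = 5)}, sigma grid
#' \code{c(0, 0.25, 0.5, 0.75, 1)}, selected values lambda = 1 (mid-grid)
#' and sigma = 0.25, at most 50 alternating cycles, relative convergence
#' tolerance 1e-4.
#'
#' @param lam,sigma selected hyperparameter values.
#' @param lamGrid,sigmaGrid search grids.
#' @param maxOuterIters,relTol,seed optimizer controls.
#' @return An [MKLConfig-class] object.
#' @export
mklConfig <- function(lam = 1, sigma = 0.25,
                      lamGrid = 2^seq(-15, 30, by = 5),
                      sigmaGrid = c(0, 0.25, 0.5, 0.75, 1),
                      maxOuterIters = 50L, relTol = 1e-4, seed = 1L) {
  new("MKLConfig", lam = lam, sigma = sigma, lamGrid = lamGrid,
      sigmaGrid = sigmaGrid, maxOuterIters = as.integer(maxOuterIters),
      relTol = relTol, seed = as.integer(seed))
}

#' Multiple-kernel learning fit
#'
#' @slot betaD,betaM learned simplex weights over the disease / miRNA base
#'   kernels.
#' @slot kdStar,kmStar the corresponding combined kernels.
#' @slot fit the [KronRLSFit-class] on the combined kernels.
#' @slot objectiveTrace regularized objective after initialization and after
#'   each alternating cycle; non-increasing by construction.
#' @export
setClass("MKLFit",
  representation(
    betaD = "KernelWeights",
    betaM = "KernelWeights",
    kdStar = "SimilarityKernel",
    kmStar = "SimilarityKernel",
    fit = "KronRLSFit",
    objectiveTrace = "numeric"
  )
)

setValidity("MKLFit", function(object) {
  tr <- object@objectiveTrace
  if (length(tr) && any(diff(tr) > 1e-9 * (1 + abs(tr[-length(tr)]))))
    return("objective trace must be non-increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## Evaluation containers
## ---------------------------------------------------------------------------

#' ROC curve with area
#'
#' @slot fpr,tpr coordinates of the curve from (0,0) to (1,1), componentwise
#'   non-decreasing.
#' @slot auc area under the curve (Mann-Whitney pair-counting value, equal to
#'   the trapezoidal integral of the points).
#' @export
setClass("RocCurve",
  representation(fpr = "numeric", tpr = "numeric", auc = "numeric")
)

setValidity("RocCurve", function(object) {
  msgs <- character()
  if (length(object@fpr) != length(object@tpr))
    msgs <- c(msgs, "fpr and tpr must have equal length")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msgs <- c(msgs, "ROC coordinates must be non-decreasing")
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must be in [0,1]")
  n <- length(object@fpr)
  if (n >= 2L) {
    trap <- sum(diff(object@fpr) *
                (object@tpr[-1L] + object@tpr[-n]) / 2)
    if (abs(trap - object@auc) > 1e-12)
      msgs <- c(msgs, "auc must equal the trapezoidal integral of the curve")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation report
#'
#' @slot mode one of "global_loocv", "local_loocv", "kfold".
#' @slot ranks data.frame with one row per held-out association: miRNA id,
#'   disease id, rank of the held-out association among its candidate set
#'   (average rank under ties) and the candidate count.
#' @slot auc overall AUC (pooled rank sweep for global mode, per-disease mean
#'   for local mode, mean over repeats for kfold).
#' @slot perDiseaseAuc named per-disease AUCs (local mode; empty otherwise).
#' @slot repeatsMean,repeatsSd mean and sd of the per-repeat AUCs (kfold
#'   mode; NA otherwise).
#' @export
setClass("CVReport",
  representation(
    mode = "character",
    ranks = "data.frame",
    auc = "numeric",
    perDiseaseAuc = "numeric",
    repeatsMean = "numeric",
    repeatsSd = "numeric"
  ),
  prototype(perDiseaseAuc = numeric(), repeatsMean = NA_real_,
            repeatsSd = NA_real_)
)

setValidity("CVReport", function(object) {
  msgs <- character()
  if (!(object@mode %in% c("global_loocv", "local_loocv", "kfold")))
    msgs <- c(msgs, "unknown cross-validation mode")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msgs <- c(msgs, "auc must be in [0,1]")
  if (nrow(object@ranks)) {
    bad <- object@ranks$rank < 1 |
      object@ranks$rank > object@ranks$candidates + 1
    if (any(bad)) msgs <- c(msgs, "ranks must lie in [1, candidates + 1]")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic fixtures
## ---------------------------------------------------------------------------

#' Specification of a synthetic planted-structure bundle
#'
#' @slot nm,nd numbers of miRNAs and diseases.
#' @slot rank latent dimension of the planted factorization.
#' @slot density fraction of entries set to 1 (strictly between 0 and 1).
#' @slot kernelNoise nonnegative mixing coefficient corrupting the
#'   informative kernels.
#' @slot nNoiseKernels number of pure-noise kernels per side.
#' @slot seed integer seed; identical specs yield identical bundles.
#' @export
setClass("SyntheticSpec",
  representation(
    nm = "integer", nd = "integer", rank = "integer", density = "numeric",
    kernelNoise = "numeric", nNoiseKernels = "integer", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@density <= 0 || object@density >= 1)
    msgs <- c(msgs, "density must be strictly between 0 and 1")
  if (object@rank < 1L) msgs <- c(msgs, "rank must be >= 1")
  if (object@kernelNoise < 0) msgs <- c(msgs, "kernelNoise must be >= 0")
  if (object@nNoiseKernels < 0L) msgs <- c(msgs, "nNoiseKernels must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Create a SyntheticSpec
#'
#' Defaults reproduce the planted instance used throughout the test suite:
#' 30 miRNAs x 20 diseases, latent rank 3, density 0.1, noiseless informative
#' kernels, one pure-noise kernel per side, seed 7.
#'
#' @param nm,nd,rank,density,kernelNoise,nNoiseKernels,seed see slots.
#' @return A [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(nm = 30L, nd = 20L, rank = 3L, density = 0.1,
                          kernelNoise = 0, nNoiseKernels = 1L, seed = 7L) {
  new("SyntheticSpec", nm = as.integer(nm), nd = as.integer(nd),
      rank = as.integer(rank), density = density, kernelNoise = kernelNoise,
      nNoiseKernels = as.integer(nNoiseKernels), seed = as.integer(seed))
}

#' Synthetic bundle: dataset, ground truth and kernels
#'
#' @slot dataset the generated [AssociationDataset-class].
#' @slot trueScores latent score matrix whose top-density entries define the
#'   observed associations.
#' @slot kernelsD,kernelsM lists of base kernels; the informative kernel
#'   comes first on each side.
#' @slot informativeD,informativeM logical flags marking informative kernels.
#' @export
setClass("SyntheticBundle",
  representation(
    dataset = "AssociationDataset",
    trueScores = "matrix",
    kernelsD = "list",
    kernelsM = "list",
    informativeD = "logical",
    informativeM = "logical"
  )
)

setValidity("SyntheticBundle", function(object) {
  msgs <- character()
  if (length(object@kernelsD) != length(object@informativeD) ||
      length(object@kernelsM) != length(object@informativeM))
    msgs <- c(msgs, "informative flags must align to the kernel lists")
  if (!identical(dim(object@trueScores), dim(object@dataset@assoc)))
    msgs <- c(msgs, "trueScores must have the dataset's dimensions")
  if (length(msgs)) msgs else TRUE
})

#' Kernel-building recipe for cross-validation
#'
#' Bundles the fixed base kernels of both sides with instructions for the
#' Gaussian interaction-profile kernels, which depend on the association
#' matrix and are rebuilt from each masked training matrix during
#' cross-validation unless \code{refold = FALSE}.
#'
#' @slot kernelsD,kernelsM lists of fixed [SimilarityKernel-class] objects
#'   (may be empty).
#' @slot addGaussian add the Gaussian interaction-profile kernel to each side.
#' @slot gammaRaw unnormalized Gaussian bandwidth.
#' @slot refold rebuild Gaussian kernels from the masked training matrix in
#'   every fold (TRUE, leakage-free) or once from the full matrix (FALSE,
#'   the cheaper leaky variant).
#' @export
setClass("KernelRecipe",
  representation(
    kernelsD = "list",
    kernelsM = "list",
    addGaussian = "logical",
    gammaRaw = "numeric",
    refold = "logical"
  ),
  prototype(addGaussian = TRUE, gammaRaw = 1, refold = TRUE)
)

setValidity("KernelRecipe", function(object) {
  if (!object@addGaussian &&
      (!length(object@kernelsD) || !length(object@kernelsM)))
    return("recipe must yield at least one kernel per side")
  if (object@gammaRaw <= 0) return("gammaRaw must be positive")
  TRUE
})

#' Create a KernelRecipe
#'
#' @param kernelsD,kernelsM fixed base kernels per side.
#' @param addGaussian,gammaRaw,refold see slots of [KernelRecipe-class].
#' @return A [KernelRecipe-class] object.
#' @export
kernelRecipe <- function(kernelsD = list(), kernelsM = list(),
                         addGaussian = TRUE, gammaRaw = 1, refold = TRUE) {
  new("KernelRecipe", kernelsD = kernelsD, kernelsM = kernelsM,
      addGaussian = addGaussian, gammaRaw = gammaRaw, refold = refold)
}
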