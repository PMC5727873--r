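## Synthetic planted-structure fixtures: low-rank bipartite datasets with
## informative and pure-noise kernels, and toy disease DAG collections.
## Draws are namespaced: each component re-seeds from the spec seed plus a
## fixed offset, so adding components never shifts existing fixtures.

.cosineNormalize <- function(M) {
  d <- diag(M)
  d[d <= 0] <- 1
  s <- 1 / sqrt(d)
  M <- M * tcrossprod(s)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

.randomFactorKernel <- function(n, r, ids, seed, name) {
  set.seed(seed)
  W <- matrix(stats::rnorm(n * r), n, r)
  SimilarityKernel(.cosineNormalize(tcrossprod(W)), ids = ids, name = name)
}

#' Corrupt a kernel with a random PSD perturbation
#'
#' Convex mixture \code{(1 - w) K + w R} with mixing weight
#' \code{w = noise / (1 + noise)} and R a random cosine-normalized PSD
#' matrix, followed by clip repair. \code{noise = 0} returns the kernel
#' untouched; as noise grows the output approaches R.
#'
#' @param k a [SimilarityKernel-class].
#' @param noise nonnegative mixing coefficient.
#' @param seed integer seed for the random perturbation.
#' @return A [SimilarityKernel-class] passing the kernel hygiene invariants.
#' @export
corruptKernel <- function(k, noise, seed = 1L) {
  stopifnot(is(k, "SimilarityKernel"))
  if (noise < 0) stop("noise must be nonnegative")
  if (noise == 0) return(k)
  n <- length(k@ids)
  R <- .randomFactorKernel(n, n, k@ids, seed, "noise")
  w <- noise / (1 + noise)
  mixed <- SimilarityKernel((1 - w) * k@matrix + w * R@matrix, ids = k@ids,
                            name = k@name, metadata = k@metadata)
  repairKernel(mixed, "clip")
}

#' Generate a planted low-rank synthetic bundle
#'
#' Latent factors U (nm x r) and V (nd x r) are drawn from a standard normal
#' stream; the true score matrix is U V' and the association matrix places a
#' 1 at its top \code{ceiling(density * nm * nd)} entries (ties broken by
#' row-major index). Informative kernels are the cosine-normalized Gram
#' matrices U U' and V V', optionally corrupted by \code{kernelNoise} (see
#' [corruptKernel()]); noise kernels are cosine-normalized Gram matrices of
#' independent random factors. The informative kernel is first in each list.
#'
#' @param spec a [SyntheticSpec-class]; identical specs yield bitwise
#'   identical bundles.
#' @return A [SyntheticBundle-class]. A density producing zero or only
#'   positive entries is an error.
#' @examples
#' b <- makeLatentBundle(syntheticSpec(nm = 10, nd = 8, density = 0.2))
#' sum(assocMatrix(b@dataset))  # 16
#' @export
makeLatentBundle <- function(spec = syntheticSpec()) {
  stopifnot(is(spec, "SyntheticSpec"))
  nm <- spec@nm; nd <- spec@nd; r <- spec@rank
  ## tolerance absorbs binary floating point in density * n (0.1 * 600 is
  ## fractionally above 60), so an exact product never rounds up
  npos <- ceiling(spec@density * nm * nd - 1e-9)
  if (npos < 1L || npos >= nm * nd)
    stop("density yields zero or all-positive entries")
  mirnas <- sprintf("m%03d", seq_len(nm))
  diseases <- sprintf("d%03d", seq_len(nd))

  set.seed(spec@seed)                       # namespace: latent factors
  U <- matrix(stats::rnorm(nm * r), nm, r)
  V <- matrix(stats::rnorm(nd * r), nd, r)
  scores <- tcrossprod(U, V)
  dimnames(scores) <- list(mirnas, diseases)

  ord <- order(-as.vector(t(scores)))       # row-major: transpose first
  rowMajor <- as.vector(t(matrix(seq_len(nm * nd), nm, nd)))
  topRowMajor <- sort(ord[seq_len(npos)])
  A <- matrix(0, nm, nd)
  A[rowMajor[topRowMajor]] <- 1
  dataset <- AssociationDataset(A, mirnas, diseases)

  infoM <- SimilarityKernel(.cosineNormalize(tcrossprod(U)), ids = mirnas,
                            name = "latentM")
  infoD <- SimilarityKernel(.cosineNormalize(tcrossprod(V)), ids = diseases,
                            name = "latentD")
  if (spec@kernelNoise > 0) {
    infoM <- corruptKernel(infoM, spec@kernelNoise, seed = spec@seed + 1000L)
    infoD <- corruptKernel(infoD, spec@kernelNoise, seed = spec@seed + 2000L)
  }
  noiseM <- lapply(seq_len(spec@nNoiseKernels), function(i)
    .randomFactorKernel(nm, r, mirnas, spec@seed + 3000L + i,
                        sprintf("noiseM%d", i)))
  noiseD <- lapply(seq_len(spec@nNoiseKernels), function(i)
    .randomFactorKernel(nd, r, diseases, spec@seed + 4000L + i,
                        sprintf("noiseD%d", i)))

  new("SyntheticBundle", dataset = dataset, trueScores = scores,
      kernelsD = c(list(infoD), noiseD), kernelsM = c(list(infoM), noiseM),
      informativeD = c(TRUE, rep(FALSE, length(noiseD))),
      informativeM = c(TRUE, rep(FALSE, length(noiseM))))
}

#' Generate a toy disease DAG collection
#'
#' Builds a shared random tree of ancestor terms (\code{depth} internal
#' levels with the given branching factor) and attaches each disease under a
#' random leaf; each disease's DAG is its ancestor path. Term document
#' frequencies follow from membership.
#'
#' @param nDiseases number of diseases.
#' @param depth tree depth (>= 1); depth 1 with branching 1 gives a single
#'   shared root.
#' @param branching children per internal node.
#' @param seed integer seed.
#' @param diseaseIds optional identifiers for the diseases (length
#'   \code{nDiseases}); defaults to "dis01", "dis02", ...
#' @return A [DAGCollection-class].
#' @export
makeToyDagCollection <- function(nDiseases = 2L, depth = 1L, branching = 1L,
                                 seed = 1L, diseaseIds = NULL) {
  if (is.null(diseaseIds)) diseaseIds <- sprintf("dis%02d", seq_len(nDiseases))
  if (length(diseaseIds) != nDiseases)
    stop("diseaseIds must have length nDiseases")
  if (depth < 1L) stop("depth must be >= 1")
  if (branching < 1L) stop("branching must be >= 1")
  set.seed(seed)
  ## level l has branching^(l-1) terms; parent of term k at level l is
  ## term ceiling(k / branching) at level l-1
  levels <- lapply(seq_len(depth), function(l)
    sprintf("t%d_%d", l, seq_len(branching^(l - 1L))))
  treeEdges <- NULL
  for (l in seq_len(depth)[-1L]) {
    for (k in seq_along(levels[[l]])) {
      treeEdges <- rbind(treeEdges,
                         c(levels[[l - 1L]][ceiling(k / branching)],
                           levels[[l]][k]))
    }
  }
  leaves <- levels[[depth]]
  pathTo <- function(leaf) {
    ## ancestor chain from root to leaf
    idx <- match(leaf, levels[[depth]])
    path <- character(depth)
    for (l in rev(seq_len(depth))) {
      path[l] <- levels[[l]][idx]
      idx <- ceiling(idx / branching)
    }
    path
  }
  dags <- lapply(seq_len(nDiseases), function(i) {
    id <- diseaseIds[i]
    leaf <- leaves[sample.int(length(leaves), 1L)]
    anc <- pathTo(leaf)
    edges <- cbind(anc[length(anc)], id)
    if (length(anc) > 1L)
      edges <- rbind(cbind(anc[-length(anc)], anc[-1L]), edges)
    DiseaseDAG(id, terms = c(id, anc), edges = edges)
  })
  DAGCollection(dags)
}

#' Write a synthetic bundle to a directory of TSV files
#'
#' Emits the association table, every kernel matrix and a toy DAG
#' collection in the package's tabular dialects, so the full file-based
#' pipeline can be exercised without external downloads.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if absent).
#' @param dagCollection optional [DAGCollection-class] to write alongside.
#' @return Invisibly, the written file paths.
#' @export
writeBundle <- function(bundle, dir, dagCollection = NULL) {
  stopifnot(is(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "associations.tsv")
  writeAssociationTable(bundle@dataset, paths)
  for (k in c(bundle@kernelsD, bundle@kernelsM)) {
    p <- file.path(dir, paste0("kernel_", k@name, ".tsv"))
    writeSimilarityMatrix(k, p)
    paths <- c(paths, p)
  }
  if (!is.null(dagCollection)) {
    p <- file.path(dir, "dags.tsv")
    writeDagEdges(dagCollection, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
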