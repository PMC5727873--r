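## Kronecker RLS: the pairwise kernel is Kd %x% Km over all
## (disease, miRNA) pairs, but the system (K + lambda I) alpha = vec(Y) is
## solved through the eigendecompositions of the two side kernels alone.
## Orientation: rows of Y are miRNAs, columns are diseases, so
## vec(Km alpha Kd) = (Kd %x% Km) vec(alpha).

.eigenCache <- new.env(parent = emptyenv())

#' Symmetric eigendecomposition of a similarity kernel
#'
#' Eigenvalues are returned in ascending order; results are cached in a
#' package-level environment keyed by a content hash of the kernel matrix,
#' so repeated decompositions across regularization values and optimizer
#' iterations are free. Downstream results are invariant to eigenvector
#' sign.
#'
#' @param k a [SimilarityKernel-class] or symmetric numeric matrix.
#' @return An [EigenFactorization-class].
#' @export
eigendecompose <- function(k) {
  M <- if (is(k, "SimilarityKernel")) k@matrix else as.matrix(k)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8)
    stop("eigendecompose requires a symmetric matrix")
  key <- rlang::hash(M)
  hit <- .eigenCache[[key]]
  if (!is.null(hit)) return(hit)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  out <- new("EigenFactorization", vectors = e$vectors[, ord, drop = FALSE],
             values = e$values[ord])
  ## bounded cache: drop everything once it grows large
  if (length(ls(.eigenCache)) > 256L)
    rm(list = ls(.eigenCache), envir = .eigenCache)
  assign(key, out, envir = .eigenCache)
  out
}

.asKernelMatrix <- function(k, what) {
  if (is(k, "SimilarityKernel")) return(k@matrix)
  M <- as.matrix(k)
  if (nrow(M) != ncol(M)) stop(sprintf("%s kernel must be square", what))
  M
}

.checkFitShapes <- function(Kd, Km, y) {
  y <- as.matrix(y)
  if (nrow(y) != nrow(Km))
    stop("label matrix rows must match the miRNA kernel dimension")
  if (ncol(y) != nrow(Kd))
    stop("label matrix columns must match the disease kernel dimension")
  y
}

.checkIdAlignment <- function(kd, km, y) {
  if (is(km, "SimilarityKernel") && !is.null(rownames(y)) &&
      !identical(.normId(rownames(y)), .normId(km@ids)))
    stop("miRNA identifiers of the label matrix and kernel are misaligned")
  if (is(kd, "SimilarityKernel") && !is.null(colnames(y)) &&
      !identical(.normId(colnames(y)), .normId(kd@ids)))
    stop("disease identifiers of the label matrix and kernel are misaligned")
  invisible(TRUE)
}

#' Fit Kronecker RLS via the eigendecomposition route
#'
#' With side eigensystems \code{Km = Qm Lm Qm'} and \code{Kd = Qd Ld Qd'},
#' the coefficient matrix is \code{C = H * (Qm' Y Qd)} (Hadamard product)
#' with filter factors \code{H[a, b] = lm[a] ld[b] / (lm[a] ld[b] + lambda)},
#' and the predicted scores are \code{F = Qm C Qd'}. This is algebraically
#' identical to solving \code{(Kd \%x\% Km + lambda I) vec(alpha) = vec(Y)}
#' and predicting \code{F = Km alpha Kd}, but never materializes the
#' pairwise kernel.
#'
#' @param kd disease-side kernel ([SimilarityKernel-class] or matrix),
#'   dimension nd.
#' @param km miRNA-side kernel, dimension nm.
#' @param y binary label matrix, nm x nd.
#' @param lam regularization parameter, >= 0. With \code{lam = 0} every
#'   eigenvalue product must exceed 1e-12 (full-rank interpolation).
#' @return A [KronRLSFit-class]. A denominator at or below 1e-12 is an
#'   error instructing the caller to repair the kernels (see
#'   [repairKernel()]); it is never silently clamped.
#' @examples
#' fit <- fitKronRLS(matrix(1), matrix(1), matrix(1), lam = 1)
#' predictedScores(fit)  # 0.5
#' @export
fitKronRLS <- function(kd, km, y, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("lam must be a single nonnegative value")
  Kd <- .asKernelMatrix(kd, "disease")
  Km <- .asKernelMatrix(km, "miRNA")
  y <- .checkFitShapes(Kd, Km, y)
  .checkIdAlignment(kd, km, y)
  em <- eigendecompose(Km)
  ed <- eigendecompose(Kd)
  P <- outer(em@values, ed@values)           # nm x nd eigenvalue products
  denom <- P + lam
  if (any(denom <= 1e-12))
    stop(paste("eigenvalue product plus lambda is <= 1e-12;",
               "repair the kernels (repairKernel) or increase lambda"))
  Ct <- crossprod(em@vectors, y) %*% ed@vectors
  C <- (P / denom) * Ct
  F <- em@vectors %*% C %*% t(ed@vectors)
  alpha <- em@vectors %*% ((Ct / denom)) %*% t(ed@vectors)
  dimnames(F) <- dimnames(alpha) <- dimnames(y)
  new("KronRLSFit", lam = lam, Cmat = C, F = F, alpha = alpha,
      Qm = em@vectors, Qd = ed@vectors)
}

#' Fit Kronecker RLS by the explicit dense solve (oracle)
#'
#' Materializes the full pairwise kernel \code{K = Kd \%x\% Km} and solves
#' \code{(K + lambda I) alpha = vec(Y)} with a dense linear solve. Cubic in
#' \code{nm * nd}, guarded to problems with at most 2000 pairs; intended as
#' the independent verification oracle for [fitKronRLS()], not for use at
#' scale.
#'
#' @inheritParams fitKronRLS
#' @return A [KronRLSFit-class] (eigenvector slots are identities; the
#'   coefficient slot holds the score matrix itself).
#' @export
fitKronRLSDirect <- function(kd, km, y, lam) {
  Kd <- .asKernelMatrix(kd, "disease")
  Km <- .asKernelMatrix(km, "miRNA")
  y <- .checkFitShapes(Kd, Km, y)
  n <- nrow(y) * ncol(y)
  if (n > 2000L)
    stop("direct solver guard: nm * nd must not exceed 2000")
  K <- Kd %x% Km
  avec <- solve(K + diag(lam, n), as.vector(y))
  fvec <- K %*% avec
  F <- matrix(fvec, nrow(y), ncol(y), dimnames = dimnames(y))
  alpha <- matrix(avec, nrow(y), ncol(y), dimnames = dimnames(y))
  new("KronRLSFit", lam = lam, Cmat = F, F = F, alpha = alpha,
      Qm = diag(nrow(y)), Qd = diag(ncol(y)))
}

#' Regularized objective of a Kronecker RLS fit
#'
#' The mean squared training loss plus the RKHS penalty:
#' \code{(1 / 2n) ||vec(Y) - vec(F)||^2 + (lambda / 2) <alpha, F>}, using
#' that \code{K vec(alpha) = vec(F)} so the quadratic form
#' \code{alpha' K alpha} equals the inner product of alpha with the scores.
#' Nonnegative for PSD kernels.
#'
#' @param fit a [KronRLSFit-class].
#' @param y the label matrix the fit was trained on.
#' @param lam regularization parameter; defaults to the fit's own.
#' @return A single numeric value.
#' @export
objectiveValue <- function(fit, y, lam = fit@lam) {
  stopifnot(is(fit, "KronRLSFit"))
  y <- as.matrix(y)
  n <- length(y)
  sum((y - fit@F)^2) / (2 * n) + (lam / 2) * sum(fit@alpha * fit@F)
}
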