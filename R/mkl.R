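## Multiple kernel learning: alternate between the KronRLS dual solution on
## the combined kernels and closed-form ridge updates of the per-side simplex
## weight vectors.

.checkKernelList <- function(kernels, what) {
  if (!length(kernels)) stop(sprintf("empty %s kernel list", what))
  if (!all(vapply(kernels, is, logical(1L), "SimilarityKernel")))
    stop(sprintf("%s kernels must be SimilarityKernel objects", what))
  ids <- kernels[[1L]]@ids
  for (k in kernels[-1L]) {
    if (!identical(.normId(k@ids), .normId(ids)))
      stop(sprintf("%s kernels disagree on identifiers", what))
  }
  invisible(ids)
}

#' Linearly combine base kernels with simplex weights
#'
#' @param kernels list of [SimilarityKernel-class] objects sharing
#'   identifiers.
#' @param weights a [KernelWeights-class] (or bare numeric simplex vector)
#'   of matching length.
#' @param name label for the combined kernel.
#' @return The entrywise weighted sum as a [SimilarityKernel-class].
#' @export
combineKernels <- function(kernels, weights, name = "combined") {
  ids <- .checkKernelList(kernels, "base")
  w <- if (is(weights, "KernelWeights")) weights@values else weights
  if (length(w) != length(kernels))
    stop("weight length must equal the number of kernels")
  M <- w[1L] * kernels[[1L]]@matrix
  for (i in seq_along(kernels)[-1L]) M <- M + w[i] * kernels[[i]]@matrix
  M <- (M + t(M)) / 2
  SimilarityKernel(M, ids = ids, name = name)
}

#' Mean-kernel initialization
#'
#' Uniform weights 1/P over the base kernels and the corresponding
#' combination (the arithmetic mean of the kernels), the starting point of
#' the alternating optimizer.
#'
#' @param kernels non-empty list of [SimilarityKernel-class] objects.
#' @return List with elements \code{kernel} ([SimilarityKernel-class]) and
#'   \code{weights} ([KernelWeights-class]).
#' @export
meanKernelInit <- function(kernels) {
  .checkKernelList(kernels, "base")
  P <- length(kernels)
  w <- KernelWeights(rep(1 / P, P))
  list(kernel = combineKernels(kernels, w, name = "mean"), weights = w)
}

#' Ridge update of one side's kernel weights
#'
#' For every base kernel on the active side, a response matrix is formed by
#' pushing the current dual coefficients through that single base kernel
#' with the other side's combined kernel held fixed
#' (\code{U_i = Km_i alpha Kd*} on the miRNA side, \code{U_i = Km* alpha
#' Kd_i} on the disease side). The weights solve the P x P ridge system
#' \code{min_beta ||vec(Y) - sum_i beta_i vec(U_i)||^2 + sigma ||beta -
#' c||^2} in closed form, are clipped at zero and renormalized to the
#' simplex. If every component clips to zero, or the base kernels are
#' numerically indistinguishable (flat objective), the incoming weights are
#' returned unchanged.
#'
#' The penalty center \code{c} is selectable. With \code{"origin"} (the
#' default) weak response matrices -- whose coefficients are least supported
#' by the data -- shrink fastest, which is what lets the optimizer separate
#' informative from noise kernels; this is the variant used by [fitMKL()].
#' With \code{"uniform"} the penalty pulls toward the uniform simplex point,
#' so the large-sigma limit is the mean-kernel combination; under the origin
#' penalty that limit is instead the label-correlation direction, because
#' the subsequent renormalization undoes global shrinkage.
#'
#' @param sideKernels list of base kernels on the side being updated.
#' @param otherCombined the fixed combined kernel of the other side.
#' @param fit the current [KronRLSFit-class] (supplies alpha).
#' @param y label matrix, nm x nd.
#' @param sigma nonnegative L2 penalty on the weight vector.
#' @param side "disease" or "mirna".
#' @param current the incoming [KernelWeights-class] (tie-break fallback).
#' @param penaltyCenter where the L2 penalty pulls: "origin" (default) or
#'   "uniform"; see Details.
#' @return A [KernelWeights-class]. A singular system at \code{sigma = 0} is
#'   an error instructing the caller to use a positive sigma.
#' @export
updateKernelWeights <- function(sideKernels, otherCombined, fit, y, sigma,
                                side = c("disease", "mirna"), current,
                                penaltyCenter = c("origin", "uniform")) {
  side <- match.arg(side)
  penaltyCenter <- match.arg(penaltyCenter)
  stopifnot(is(fit, "KronRLSFit"), is(current, "KernelWeights"))
  if (sigma < 0) stop("sigma must be nonnegative")
  P <- length(sideKernels)
  if (length(current@values) != P)
    stop("incoming weights must match the number of base kernels")
  if (P == 1L) return(KernelWeights(1))
  Kother <- .asKernelMatrix(otherCombined, "combined")
  alpha <- fit@alpha
  U <- lapply(sideKernels, function(k) {
    Ki <- k@matrix
    if (side == "mirna") Ki %*% alpha %*% Kother
    else Kother %*% alpha %*% Ki
  })
  ## flat objective: all response matrices coincide -> keep current weights
  spread <- max(vapply(U[-1L], function(u) max(abs(u - U[[1L]])),
                       numeric(1L)))
  if (spread < 1e-10) return(current)
  G <- vapply(U, as.vector, numeric(length(y)))
  gram <- crossprod(G)
  if (sigma == 0 && rcond(gram) < 1e-12)
    stop("singular weight system with sigma = 0; use a positive sigma")
  center <- if (penaltyCenter == "uniform") rep(1 / P, P) else numeric(P)
  beta <- solve(gram + diag(sigma, P),
                crossprod(G, as.vector(y)) + sigma * center)
  beta <- pmax(as.vector(beta), 0)
  if (sum(beta) <= 0) return(current)
  KernelWeights(beta / sum(beta))
}

#' Fit the multiple-kernel Kronecker RLS model
#'
#' Both sides start from the mean-kernel initialization. Each outer cycle
#' (1) solves the KronRLS problem on the current combined kernels, (2)
#' proposes new disease-side weights with the miRNA combination fixed,
#' recombines and re-solves, then (3) does the same for the miRNA side. A
#' proposed update that would increase the regularized objective is rejected
#' and that side's weights are frozen for the remainder, which guarantees a
#' non-increasing objective trace. The loop stops when the relative
#' objective decrease over a full cycle falls below \code{relTol}, when both
#' sides are frozen, or after \code{maxOuterIters} cycles.
#'
#' @param kernelsD,kernelsM lists of base kernels for the disease / miRNA
#'   side, aligned to the label matrix.
#' @param y binary label matrix, nm x nd.
#' @param lam regularization parameter, > 0; defaults to the configured
#'   value.
#' @param config an [MKLConfig-class]; supplies \code{sigma},
#'   \code{maxOuterIters} and \code{relTol}.
#' @return An [MKLFit-class].
#' @export
fitMKL <- function(kernelsD, kernelsM, y, lam = config@lam,
                   config = mklConfig()) {
  idsD <- .checkKernelList(kernelsD, "disease")
  idsM <- .checkKernelList(kernelsM, "miRNA")
  y <- as.matrix(y)
  if (nrow(y) != length(idsM) || ncol(y) != length(idsD))
    stop("label matrix dimensions do not match the kernel lists")
  if (lam <= 0) stop("lam must be positive for the MKL optimizer")
  sigma <- config@sigma

  initD <- meanKernelInit(kernelsD)
  initM <- meanKernelInit(kernelsM)
  betaD <- initD$weights; betaM <- initM$weights
  kdStar <- initD$kernel; kmStar <- initM$kernel
  fit <- fitKronRLS(kdStar, kmStar, y, lam)
  obj <- objectiveValue(fit, y, lam)
  trace <- obj
  frozenD <- length(kernelsD) == 1L
  frozenM <- length(kernelsM) == 1L

  for (iter in seq_len(config@maxOuterIters)) {
    if (!frozenD) {
      cand <- updateKernelWeights(kernelsD, kmStar, fit, y, sigma,
                                  side = "disease", current = betaD)
      kdCand <- combineKernels(kernelsD, cand, name = "Kd*")
      fitCand <- fitKronRLS(kdCand, kmStar, y, lam)
      objCand <- objectiveValue(fitCand, y, lam)
      if (objCand <= obj + 1e-12 * (1 + abs(obj))) {
        betaD <- cand; kdStar <- kdCand; fit <- fitCand; obj <- objCand
      } else frozenD <- TRUE
    }
    if (!frozenM) {
      cand <- updateKernelWeights(kernelsM, kdStar, fit, y, sigma,
                                  side = "mirna", current = betaM)
      kmCand <- combineKernels(kernelsM, cand, name = "Km*")
      fitCand <- fitKronRLS(kdStar, kmCand, y, lam)
      objCand <- objectiveValue(fitCand, y, lam)
      if (objCand <= obj + 1e-12 * (1 + abs(obj))) {
        betaM <- cand; kmStar <- kmCand; fit <- fitCand; obj <- objCand
      } else frozenM <- TRUE
    }
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (frozenD && frozenM) break
    if ((prev - obj) < config@relTol * max(abs(prev), 1e-12)) break
  }
  kdStar@name <- "Kd*"; kmStar@name <- "Km*"
  new("MKLFit", betaD = betaD, betaM = betaM, kdStar = kdStar,
      kmStar = kmStar, fit = fit, objectiveTrace = trace)
}

#' Select lambda and sigma by inner cross-validation
#'
#' Grid search over the configured lambda and sigma grids, scoring each pair
#' by the mean AUC of an inner k-fold cross-validation over the known
#' associations (held-out positives ranked against all unknown pairs).
#' Deterministic given the seed. With \code{folds = 0} selection is disabled
#' and the documented defaults (lambda = 1, sigma = 0.25) are returned;
#' single-point grids are returned without running any CV.
#'
#' @param kernelsD,kernelsM base kernel lists.
#' @param y binary label matrix.
#' @param config an [MKLConfig-class] supplying the grids.
#' @param folds number of inner folds (default 3); 0 disables selection.
#' @param seed integer seed for the fold assignment.
#' @return The input config with \code{lam} and \code{sigma} replaced by the
#'   selected values, plus an attribute \code{"aucGrid"} holding the mean
#'   inner AUC of every grid point.
#' @export
selectHyperparameters <- function(kernelsD, kernelsM, y,
                                  config = mklConfig(), folds = 3L,
                                  seed = config@seed) {
  if (!length(config@lamGrid) || !length(config@sigmaGrid))
    stop("hyperparameter grids must be non-empty")
  if (folds == 0L) {
    config@lam <- 1; config@sigma <- 0.25
    return(config)
  }
  if (folds < 2L) stop("folds must be 0 or >= 2")
  y <- as.matrix(y)
  if (length(config@lamGrid) == 1L && length(config@sigmaGrid) == 1L) {
    config@lam <- config@lamGrid; config@sigma <- config@sigmaGrid
    return(config)
  }
  pos <- which(y == 1)
  if (length(pos) < folds) stop("fewer known associations than folds")
  set.seed(seed)
  assign <- sample(rep(seq_len(folds), length.out = length(pos)))
  grid <- expand.grid(lam = config@lamGrid, sigma = config@sigmaGrid)
  grid$auc <- NA_real_
  candidates <- which(y == 0)
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg@lam <- grid$lam[g]; cfg@sigma <- grid$sigma[g]
    aucs <- vapply(seq_len(folds), function(f) {
      test <- pos[assign == f]
      ytr <- y; ytr[test] <- 0
      mfit <- fitMKL(kernelsD, kernelsM, ytr, lam = cfg@lam, config = cfg)
      s <- mfit@fit@F
      .pooledRankAuc(s, test, candidates)
    }, numeric(1L))
    grid$auc[g] <- mean(aucs)
  }
  best <- which.max(grid$auc)
  config@lam <- grid$lam[best]
  config@sigma <- grid$sigma[best]
  attr(config, "aucGrid") <- grid
  config
}
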