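## Cross-validation protocols and ROC/AUC. Ranking convention: a held-out
## association is ranked against a candidate set with average rank under
## ties (0.5 credit), the standard Mann-Whitney treatment.

#' ROC curve and AUC by Mann-Whitney pair counting
#'
#' The AUC is the fraction of (positive, negative) score pairs in which the
#' positive outranks the negative, with ties counting 0.5 -- identical to
#' trapezoidal integration of the ROC curve, which is also returned
#' (one point per distinct threshold, from (0,0) to (1,1)).
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary vector (0/1 or logical) of the same length; at least
#'   one positive and one negative are required.
#' @return A [RocCurve-class].
#' @examples
#' auc(rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores)                      # average rank under ties
  aucVal <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ## threshold sweep over distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))          # tie groups share a threshold
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  new("RocCurve", fpr = fpr, tpr = tpr, auc = aucVal)
}

## AUC of held-out entries against a shared candidate set, pooled over
## leave-outs by rank-threshold sweep. Each test entry is scored by its own
## fold's model; candidate scores come from the same fold. With a common
## candidate count the pooled sweep equals the mean per-test Mann-Whitney
## value, which is what this computes.
.rankAgainst <- function(testScore, candScores) {
  ngreater <- sum(candScores > testScore)
  nties <- sum(candScores == testScore)
  ngreater + 0.5 * nties + 1
}

.pooledRankAuc <- function(scoreMatrix, testIdx, candidateIdx) {
  cand <- scoreMatrix[candidateIdx]
  n <- length(cand)
  aucs <- vapply(testIdx, function(p) {
    r <- .rankAgainst(scoreMatrix[p], cand)
    (n + 1 - r) / n
  }, numeric(1L))
  mean(aucs)
}

#' Build the kernel lists of a recipe for a (possibly masked) dataset
#'
#' Returns the recipe's fixed kernels, with the Gaussian interaction-profile
#' kernels of both sides appended when requested. During cross-validation
#' the Gaussian kernels are rebuilt from each masked training matrix, so the
#' held-out labels never leak into the profiles.
#'
#' @param recipe a [KernelRecipe-class].
#' @param dataset the (training) [AssociationDataset-class].
#' @return List with elements \code{d} and \code{m}, each a list of
#'   [SimilarityKernel-class] objects.
#' @export
buildKernels <- function(recipe, dataset) {
  stopifnot(is(recipe, "KernelRecipe"), is(dataset, "AssociationDataset"))
  kd <- recipe@kernelsD
  km <- recipe@kernelsM
  if (recipe@addGaussian) {
    kd <- c(kd, list(gaussianProfileKernel(dataset, "disease",
                                           recipe@gammaRaw)))
    km <- c(km, list(gaussianProfileKernel(dataset, "mirna",
                                           recipe@gammaRaw)))
  }
  list(d = kd, m = km)
}

.maskedDataset <- function(dataset, maskIdx) {
  A <- dataset@assoc
  A[maskIdx] <- 0
  AssociationDataset(A, dataset@mirnaIds, dataset@diseaseIds)
}

.fitForFold <- function(dataset, recipe, config, maskIdx,
                        staticKernels = NULL) {
  train <- .maskedDataset(dataset, maskIdx)
  ks <- if (recipe@refold || is.null(staticKernels))
    buildKernels(recipe, train) else staticKernels
  fitMKL(ks$d, ks$m, train@assoc, lam = config@lam, config = config)
}

.staticKernelsIfLeaky <- function(dataset, recipe) {
  if (recipe@refold) NULL else buildKernels(recipe, dataset)
}

#' Global leave-one-out cross-validation
#'
#' Every known association is left out in turn: its entry is zeroed in a
#' training copy, Gaussian kernels are rebuilt from the masked matrix
#' (unless \code{recipe@refold} is FALSE), the multiple-kernel model is
#' refit, and the held-out pair is ranked against all unknown pairs of the
#' original matrix. The overall AUC pools the leave-out ranks through a
#' common rank-threshold sweep (all leave-outs share the candidate set).
#'
#' @param dataset an [AssociationDataset-class] with at least 2 known
#'   associations.
#' @param recipe a [KernelRecipe-class].
#' @param config an [MKLConfig-class].
#' @return A [CVReport-class] with mode "global_loocv".
#' @export
globalLoocv <- function(dataset, recipe, config = mklConfig()) {
  A <- assocMatrix(dataset)
  pos <- which(A == 1)
  if (length(pos) < 2L)
    stop("global LOOCV needs at least 2 known associations")
  cand <- which(A == 0)
  static <- .staticKernelsIfLeaky(dataset, recipe)
  nCand <- length(cand)
  ranks <- numeric(length(pos))
  aucs <- numeric(length(pos))
  for (t in seq_along(pos)) {
    p <- pos[t]
    mfit <- .fitForFold(dataset, recipe, config, p, static)
    s <- mfit@fit@F
    r <- .rankAgainst(s[p], s[cand])
    ranks[t] <- r
    aucs[t] <- (nCand + 1 - r) / nCand
  }
  ij <- arrayInd(pos, dim(A))
  rep <- data.frame(
    mirna = dataset@mirnaIds[ij[, 1L]],
    disease = dataset@diseaseIds[ij[, 2L]],
    rank = ranks, candidates = nCand, stringsAsFactors = FALSE)
  new("CVReport", mode = "global_loocv", ranks = rep, auc = mean(aucs))
}

#' Local (per-disease) leave-one-out cross-validation
#'
#' For each evaluated disease, each of its known miRNAs is left out in turn
#' and ranked only against that disease's candidate miRNAs (those without a
#' known association). Per-disease AUCs come from the per-disease rank
#' sweep; the report's AUC is their mean. Diseases without any known miRNA
#' are skipped with a warning.
#'
#' @inheritParams globalLoocv
#' @param diseases optional character vector restricting evaluation to the
#'   named diseases.
#' @return A [CVReport-class] with mode "local_loocv" and per-disease AUCs.
#' @export
localLoocv <- function(dataset, recipe, config = mklConfig(),
                       diseases = NULL) {
  A <- assocMatrix(dataset)
  if (is.null(diseases)) diseases <- diseaseIds(dataset)
  unknown <- setdiff(diseases, diseaseIds(dataset))
  if (length(unknown))
    stop(sprintf("unknown disease(s): %s", paste(unknown, collapse = ", ")))
  static <- .staticKernelsIfLeaky(dataset, recipe)
  perDisease <- numeric(0)
  rows <- list()
  for (d in diseases) {
    j <- match(d, diseaseIds(dataset))
    posM <- which(A[, j] == 1)
    if (!length(posM)) {
      warning(sprintf("disease '%s' has no known miRNAs; skipped", d))
      next
    }
    candM <- which(A[, j] == 0)
    if (!length(candM)) {
      warning(sprintf("disease '%s' has no candidate miRNAs; skipped", d))
      next
    }
    aucs <- numeric(length(posM))
    for (t in seq_along(posM)) {
      i <- posM[t]
      mfit <- .fitForFold(dataset, recipe, config,
                          matrix(c(i, j), 1L), static)
      s <- mfit@fit@F
      r <- .rankAgainst(s[i, j], s[candM, j])
      aucs[t] <- (length(candM) + 1 - r) / length(candM)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = dataset@mirnaIds[i], disease = d, rank = r,
        candidates = length(candM), stringsAsFactors = FALSE)
    }
    perDisease[d] <- mean(aucs)
  }
  if (!length(perDisease))
    stop("no evaluable disease (none has both known and candidate miRNAs)")
  new("CVReport", mode = "local_loocv",
      ranks = do.call(rbind, rows), auc = mean(perDisease),
      perDiseaseAuc = perDisease)
}

#' Repeated k-fold cross-validation over known associations
#'
#' The known associations are partitioned uniformly at random into k groups
#' of near-equal size (differing by at most 1). Each group is masked in
#' turn, the model refit on the remainder, and the held-out associations
#' ranked against all unknown pairs; the per-repeat AUC pools the ranks of
#' one full partition. Reported are the mean and standard deviation over
#' repeats; everything is reproducible from the seed.
#'
#' @inheritParams globalLoocv
#' @param k number of folds (>= 2 and at most the number of positives).
#' @param repeats number of random re-partitions (default 5).
#' @param seed integer seed for the partitions.
#' @return A [CVReport-class] with mode "kfold"; the rank table covers the
#'   last repeat.
#' @export
kfoldCv <- function(dataset, recipe, config = mklConfig(), k = 5L,
                    repeats = 5L, seed = 42L) {
  A <- assocMatrix(dataset)
  pos <- which(A == 1)
  if (k < 2L) stop("k must be >= 2")
  if (length(pos) < k) stop("fewer known associations than folds")
  cand <- which(A == 0)
  static <- .staticKernelsIfLeaky(dataset, recipe)
  set.seed(seed)
  repAucs <- numeric(repeats)
  lastRows <- NULL
  for (r in seq_len(repeats)) {
    assign <- sample(rep(seq_len(k), length.out = length(pos)))
    ranks <- numeric(length(pos))
    for (f in seq_len(k)) {
      test <- pos[assign == f]
      mfit <- .fitForFold(dataset, recipe, config, test, static)
      s <- mfit@fit@F
      for (p in test)
        ranks[match(p, pos)] <- .rankAgainst(s[p], s[cand])
    }
    n <- length(cand)
    repAucs[r] <- mean((n + 1 - ranks) / n)
    if (r == repeats) {
      ij <- arrayInd(pos, dim(A))
      lastRows <- data.frame(
        mirna = dataset@mirnaIds[ij[, 1L]],
        disease = dataset@diseaseIds[ij[, 2L]],
        rank = ranks, candidates = n, stringsAsFactors = FALSE)
    }
  }
  new("CVReport", mode = "kfold", ranks = lastRows, auc = mean(repAucs),
      repeatsMean = mean(repAucs),
      repeatsSd = if (repeats > 1L) stats::sd(repAucs) else NA_real_)
}
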