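test_that("model-1 contributions decay geometrically from the disease", {
  solo <- DiseaseDAG("d1")
  expect_equal(semanticContributionsModel1(solo, 0.5)@contributions,
               c(d1 = 1))

  parent <- DiseaseDAG("d1", terms = c("d1", "P"), edges = rbind(c("P", "d1")))
  cm <- semanticContributionsModel1(parent, 0.5)
  expect_equal(cm@contributions[c("d1", "P")], c(d1 = 1, P = 0.5))
  expect_equal(semanticValue(cm), 1.5)

  chain <- DiseaseDAG("d1", terms = c("d1", "P", "G"),
                      edges = rbind(c("G", "P"), c("P", "d1")))
  cm2 <- semanticContributionsModel1(chain, 0.5)
  expect_equal(cm2@contributions[c("d1", "P", "G")],
               c(d1 = 1, P = 0.5, G = 0.25))
  expect_equal(semanticValue(cm2), 1.75)

  # multi-parent layer: both take the same (max over children) score
  diamond <- DiseaseDAG("d", terms = c("d", "A", "B", "R"),
                        edges = rbind(c("A", "d"), c("B", "d"),
                                      c("R", "A"), c("R", "B")))
  cm3 <- semanticContributionsModel1(diamond, 0.5)
  expect_equal(unname(cm3@contributions[c("A", "B")]), c(0.5, 0.5))
  expect_equal(unname(cm3@contributions["R"]), 0.25)

  expect_error(semanticContributionsModel1(solo, 0), "delta")
  expect_error(semanticContributionsModel1(solo, 1.2), "delta")
})

test_that("model-1 similarity matches hand values and is a valid kernel", {
  col <- sharedParentDags()
  ss1 <- semanticSimilarityModel1(col, delta = 0.5)
  M <- kernelMatrix(ss1)
  expect_equal(unname(diag(M)), c(1, 1))
  expect_equal(M[1, 2], 1 / 3, tolerance = 1e-12)

  disjoint <- DAGCollection(list(DiseaseDAG("d1"), DiseaseDAG("d2")))
  expect_equal(kernelMatrix(semanticSimilarityModel1(disjoint))[1, 2], 0)

  expect_error(semanticSimilarityModel1(col, diseaseIds = c("d1", "zz")),
               "no DAG")
})

test_that("model-1 similarity is monotone in shared ancestry (chains, depth <= 3)", {
  for (distinct in 0:2) {
    prev <- -Inf
    for (shared in 0:3) {
      if (shared + distinct == 0) next
      val <- kernelMatrix(
        semanticSimilarityModel1(chainPairDags(shared, distinct), 0.5))[1, 2]
      expect_gte(val, prev)
      prev <- val
    }
  }
})

test_that("model-2 contributions follow -log document frequency", {
  col2 <- sharedParentDags()                      # nd = 2, P in both DAGs
  maps <- semanticContributionsModel2(col2)
  expect_equal(unname(maps$d1@contributions["P"]), 0)    # ubiquitous term
  expect_equal(unname(maps$d1@contributions["d1"]), -log(0.5),
               tolerance = 1e-12)
  # identical term -> identical contribution across diseases
  expect_identical(maps$d1@contributions["P"], maps$d2@contributions["P"])

  # nd = 4, a term present in 2 DAGs scores -log(1/2) as well
  col4 <- DAGCollection(list(
    DiseaseDAG("d1", c("d1", "T"), rbind(c("T", "d1"))),
    DiseaseDAG("d2", c("d2", "T"), rbind(c("T", "d2"))),
    DiseaseDAG("d3"), DiseaseDAG("d4")))
  m4 <- semanticContributionsModel2(col4)
  expect_equal(unname(m4$d1@contributions["T"]), -log(2 / 4),
               tolerance = 1e-12)
})

test_that("model-2 similarity zeroes out ubiquitous-only overlap", {
  col <- sharedParentDags()   # shared parent is in every DAG -> D2 = 0
  ss2 <- semanticSimilarityModel2(col)
  expect_equal(kernelMatrix(ss2)[1, 2], 0)
  expect_equal(unname(diag(kernelMatrix(ss2))), c(1, 1))

  disjoint <- DAGCollection(list(DiseaseDAG("d1"), DiseaseDAG("d2")))
  expect_equal(kernelMatrix(semanticSimilarityModel2(disjoint))[1, 2], 0)

  # a disease whose every term is ubiquitous has zero semantic value:
  # diagonal falls back to 1 with a warning
  solo <- DAGCollection(list(DiseaseDAG("only")))
  expect_warning(k <- semanticSimilarityModel2(solo), "zero semantic value")
  expect_equal(kernelMatrix(k), matrix(1, dimnames = list("only", "only")))
})

test_that("Gaussian profile kernels reproduce the hand-computed toy values", {
  ds <- toyAssociation()
  gd <- gaussianProfileKernel(ds, "disease", gammaRaw = 1)
  gm <- gaussianProfileKernel(ds, "mirna", gammaRaw = 1)
  expect_equal(kernelMatrix(gd)["d1", "d2"], exp(-1), tolerance = 1e-12)
  expect_equal(kernelMatrix(gm)["m1", "m2"], exp(-1.5), tolerance = 1e-12)
  expect_equal(gd@metadata$bandwidth@gamma, 0.5)
  expect_equal(gm@metadata$bandwidth@gamma, 0.75)

  # identical profiles score exactly 1
  ds2 <- AssociationDataset(rbind(c(1, 1), c(1, 1), c(0, 0)))
  expect_equal(kernelMatrix(gaussianProfileKernel(ds2, "disease"))[1, 2], 1)

  empty <- AssociationDataset(matrix(0, 2, 2))
  expect_error(gaussianProfileKernel(empty, "disease"), "bandwidth")
  expect_error(gaussianBandwidth(ds, "disease", gammaRaw = 0), "positive")
})

test_that("Gaussian kernels transform consistently under miRNA permutation", {
  set.seed(5)
  A <- randomBinaryMatrix(8, 6, seed = 5)
  ds <- AssociationDataset(A)
  perm <- sample(8)
  dsP <- AssociationDataset(A[perm, ], mirnaIds = mirnaIds(ds)[perm],
                            diseaseIds = diseaseIds(ds))
  # disease kernel is invariant, miRNA kernel is conjugated
  expect_equal(kernelMatrix(gaussianProfileKernel(dsP, "disease")),
               kernelMatrix(gaussianProfileKernel(ds, "disease")),
               tolerance = 1e-12)
  expect_equal(unname(kernelMatrix(gaussianProfileKernel(dsP, "mirna"))),
               unname(kernelMatrix(gaussianProfileKernel(ds, "mirna"))[perm, perm]),
               tolerance = 1e-12)
})

test_that("functional similarity integrates over the Gaussian background", {
  gm <- randomPsdKernel(5, seed = 3, ids = paste0("m", 1:5))
  fsM <- matrix(c(1, 0.7, 0.7, 1), 2)
  fs <- SimilarityKernel(fsM, ids = c("m2", "m4"), name = "FS")
  out <- integrateMirnaSimilarity(fs, gm)
  expect_equal(kernelIds(out), kernelIds(gm))
  expect_equal(kernelMatrix(out)["m2", "m4"], 0.7)          # both covered
  expect_equal(kernelMatrix(out)["m1", "m2"],
               kernelMatrix(gm)["m1", "m2"])                # uncovered
  expect_equal(unname(diag(kernelMatrix(out))), rep(1, 5))

  bad <- SimilarityKernel(fsM, ids = c("m2", "zz"))
  expect_error(integrateMirnaSimilarity(bad, gm), "absent")
})

test_that("kernel repair clips negative spectra and restores a unit diagonal", {
  # indefinite toy matrix [[1,2],[2,1]] has eigenvalues 3 and -1
  k <- SimilarityKernel(rbind(c(1, 2), c(2, 1)), ids = c("a", "b"))
  rep <- repairKernel(k, "clip")
  expect_gte(min(eigen(kernelMatrix(rep), symmetric = TRUE)$values), -1e-12)
  expect_equal(rep@metadata$lambdaMinBefore, -1)
  expect_equal(unname(diag(kernelMatrix(rep))), c(1, 1))

  sh <- repairKernel(k, "shift")
  expect_gte(min(eigen(kernelMatrix(sh), symmetric = TRUE)$values), -1e-10)

  # PSD input under clip: just cosine normalization
  psd <- randomPsdKernel(4, seed = 8)
  expect_equal(kernelMatrix(repairKernel(psd, "clip")), kernelMatrix(psd),
               tolerance = 1e-10)
  # none: untouched passthrough
  expect_identical(repairKernel(k, "none"), k)
})

test_that("produced kernels satisfy the hygiene invariants", {
  ds <- toyAssociation()
  col <- makeToyDagCollection(nDiseases = 5, depth = 3, branching = 2, seed = 4)
  kernels <- list(
    gaussianProfileKernel(ds, "disease"),
    gaussianProfileKernel(ds, "mirna"),
    semanticSimilarityModel1(col),
    suppressWarnings(semanticSimilarityModel2(col))
  )
  for (k in kernels) {
    M <- kernelMatrix(k)
    expect_lte(max(abs(M - t(M))), 1e-10)
    expect_lte(max(abs(diag(M) - 1)), 1e-10)
    expect_gte(min(M), 0)
    expect_lte(max(M), 1 + 1e-12)
  }
})
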