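test_that("association tables collapse duplicates and keep first-appearance order", {
  tf <- withr::local_tempfile()
  writeLines(c("m1\td1", "m2\td2", "m1\td1"), tf)
  ds <- suppressMessages(readAssociationTable(tf))
  expect_equal(mirnaIds(ds), c("m1", "m2"))
  expect_equal(diseaseIds(ds), c("d1", "d2"))
  expect_equal(unname(assocMatrix(ds)), rbind(c(1, 0), c(0, 1)))

  tf2 <- withr::local_tempfile()
  writeLines("m1\td1", tf2)
  ds1 <- readAssociationTable(tf2)
  expect_equal(dim(assocMatrix(ds1)), c(1L, 1L))
  expect_equal(unname(assocMatrix(ds1)), matrix(1))
})

test_that("association parsing is idempotent under row duplication", {
  rows <- c("mA\tdX", "mB\tdY", "mA\tdY", "mC\tdX")
  t1 <- withr::local_tempfile(); writeLines(rows, t1)
  t2 <- withr::local_tempfile(); writeLines(rep(rows, 3), t2)
  d1 <- readAssociationTable(t1)
  d2 <- suppressMessages(readAssociationTable(t2))
  expect_identical(assocMatrix(d1), assocMatrix(d2))
  expect_identical(mirnaIds(d1), mirnaIds(d2))
})

test_that("identifier matching trims whitespace and ignores case", {
  tf <- withr::local_tempfile()
  writeLines(c("hsa-miR-21 \tColonic Neoplasms", "HSA-MIR-21\tcolonic neoplasms "),
             tf)
  ds <- suppressMessages(readAssociationTable(tf))
  expect_equal(nMirnas(ds), 1L)
  expect_equal(nDiseases(ds), 1L)
  expect_equal(mirnaIds(ds), "hsa-miR-21")  # first-seen spelling kept
})

test_that("malformed or empty association input is rejected with a line number", {
  tf <- withr::local_tempfile()
  writeLines(c("m1\td1", "lonely-field"), tf)
  expect_error(readAssociationTable(tf), "line 2")
  t2 <- withr::local_tempfile(); writeLines("# only a comment", t2)
  expect_error(readAssociationTable(t2), "no association rows")
})

test_that("write/read round-trip preserves the matrix and both id orders", {
  set.seed(11)
  A <- matrix(rbinom(35, 1, 0.3), 7, 5)
  A[3, ] <- 0  # miRNA with no association survives via directives
  ds <- AssociationDataset(A, mirnaIds = paste0("mir", sample(7)),
                           diseaseIds = paste0("dis", sample(5)))
  tf <- withr::local_tempfile()
  writeAssociationTable(ds, tf)
  back <- readAssociationTable(tf)
  expect_identical(assocMatrix(back), assocMatrix(ds))
  expect_identical(mirnaIds(back), mirnaIds(ds))
  expect_identical(diseaseIds(back), diseaseIds(ds))
})

test_that("similarity matrices symmetrize tiny asymmetry and reject large", {
  k <- randomPsdKernel(4, seed = 2, ids = c("a", "b", "c", "d"))
  tf <- withr::local_tempfile()
  writeSimilarityMatrix(k, tf)
  back <- readSimilarityMatrix(tf)
  expect_equal(kernelMatrix(back), kernelMatrix(k), tolerance = 1e-12)
  expect_equal(kernelIds(back), kernelIds(k))

  writeAsym <- function(gap) {
    M <- kernelMatrix(k)
    M[1, 2] <- M[2, 1] + gap
    path <- withr::local_tempfile(.local_envir = parent.frame(2L))
    writeLines(c(paste(c("", kernelIds(k)), collapse = "\t"),
                 vapply(1:4, function(r)
                   paste(c(kernelIds(k)[r],
                           format(M[r, ], digits = 17)), collapse = "\t"), "")),
               path)
    path
  }
  sym <- readSimilarityMatrix(writeAsym(1e-8))
  expect_equal(kernelMatrix(sym)[1, 2], kernelMatrix(k)[2, 1] + 5e-9,
               tolerance = 1e-10)
  expect_error(readSimilarityMatrix(writeAsym(0.1)), "asymmetry")
})

test_that("similarity reader rejects non-square bodies and id mismatches", {
  tf <- withr::local_tempfile()
  writeLines(c("\ta\tb", "a\t1\t0"), tf)
  expect_error(readSimilarityMatrix(tf), "non-square")
  t2 <- withr::local_tempfile()
  writeLines(c("\ta\tb", "a\t1\t0", "c\t0\t1"), t2)
  expect_error(readSimilarityMatrix(t2), "identifiers")
})

test_that("DAG edge lists build per-disease graphs and shared term frequencies", {
  tf <- withr::local_tempfile()
  writeLines(c("d1\td1\tP", "d2\td2\tP"), tf)
  col <- readDagEdges(tf)
  expect_setequal(col@dags$d1@terms, c("d1", "P"))
  expect_equal(unname(col@dags$d1@edges), rbind(c("P", "d1")))
  expect_equal(col@termFrequency[["P"]], 2L)
  expect_equal(col@termFrequency[["d1"]], 1L)

  # root declaration via empty parent
  t2 <- withr::local_tempfile()
  writeLines(c("d1\td1\t"), t2)
  solo <- readDagEdges(t2)
  expect_equal(nrow(solo@dags$d1@edges), 0L)
})

test_that("a cyclic disease DAG is rejected by name", {
  tf <- withr::local_tempfile()
  writeLines(c("d1\td1\tP", "d1\tP\td1"), tf)
  expect_error(readDagEdges(tf), "cycle.*'d1'")
})

test_that("term frequencies equal brute-force membership counts", {
  col <- makeToyDagCollection(nDiseases = 6, depth = 3, branching = 2,
                              seed = 9)
  brute <- table(unlist(lapply(col@dags, function(d) unique(d@terms))))
  expect_equal(sort(col@termFrequency),
               sort(setNames(as.integer(brute), names(brute))))
})

test_that("prediction tables rank candidates per disease, excluding knowns", {
  ds <- AssociationDataset(rbind(c(0), c(0)), mirnaIds = c("m1", "m2"),
                           diseaseIds = "d1")
  tf <- withr::local_tempfile()
  writePredictionTable(rbind(0.9, 0.2), ds, tf)
  tab <- read.delim(tf)
  expect_equal(tab$rank[tab$mirna_id == "m1"], 1L)
  expect_equal(tab$rank[tab$mirna_id == "m2"], 2L)

  # known association excluded from candidate ranks; ties broken by id
  ds2 <- AssociationDataset(rbind(c(1), c(0), c(0)),
                            mirnaIds = c("mz", "mb", "ma"), diseaseIds = "d1")
  t2 <- withr::local_tempfile()
  writePredictionTable(rbind(5, 0.5, 0.5), ds2, t2)
  tab2 <- read.delim(t2)
  expect_true(is.na(tab2$rank[tab2$mirna_id == "mz"]))
  expect_equal(tab2$known_flag[tab2$mirna_id == "mz"], 1L)
  expect_equal(tab2$rank[tab2$mirna_id == "ma"], 1L)  # tie -> lexicographic
  expect_equal(tab2$rank[tab2$mirna_id == "mb"], 2L)

  expect_error(writePredictionTable(matrix(0, 2, 2), ds2, t2), "shape")
})
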