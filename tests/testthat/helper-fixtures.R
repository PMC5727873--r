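# Shared fixtures, built in code.

# random PSD kernel with unit diagonal (cosine-normalized Gram matrix)
randomPsdKernel <- function(n, seed, rank = n, ids = paste0("x", seq_len(n))) {
  set.seed(seed)
  W <- matrix(rnorm(n * rank), n, rank)
  M <- tcrossprod(W)
  s <- 1 / sqrt(diag(M))
  M <- M * tcrossprod(s)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  SimilarityKernel(M, ids = ids, name = sprintf("psd%d", seed))
}

randomBinaryMatrix <- function(nm, nd, seed, p = 0.3) {
  set.seed(seed)
  repeat {
    y <- matrix(rbinom(nm * nd, 1, p), nm, nd)
    if (sum(y) >= 2 && sum(y) < nm * nd) return(y)
  }
}

# all-pairs AUC oracle: concordant + half ties over pos x neg pairs
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# the toy association matrix used in the worked kernel examples:
# 3 miRNAs x 2 diseases
toyAssociation <- function() {
  AssociationDataset(rbind(c(1, 0), c(0, 1), c(1, 1)),
                     mirnaIds = c("m1", "m2", "m3"),
                     diseaseIds = c("d1", "d2"))
}

# two diseases hanging under one shared parent term
sharedParentDags <- function() {
  DAGCollection(list(
    DiseaseDAG("d1", terms = c("d1", "P"), edges = rbind(c("P", "d1"))),
    DiseaseDAG("d2", terms = c("d2", "P"), edges = rbind(c("P", "d2")))
  ))
}

# chain DAGs for two diseases: `shared` common ancestors on top of
# `distinct` private ancestors each
chainPairDags <- function(shared, distinct) {
  mk <- function(id) {
    priv <- if (distinct > 0) paste0(id, "_a", seq_len(distinct)) else character()
    comm <- if (shared > 0) paste0("S", seq_len(shared)) else character()
    chain <- c(rev(comm), rev(priv), id)   # root ... leaf
    edges <- if (length(chain) > 1)
      cbind(chain[-length(chain)], chain[-1]) else NULL
    DiseaseDAG(id, terms = chain, edges = edges)
  }
  DAGCollection(list(mk("d1"), mk("d2")))
}

plantedBundle <- function(...) makeLatentBundle(syntheticSpec(...))

plantedConfig <- function() mklConfig(lam = 2^-5)
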