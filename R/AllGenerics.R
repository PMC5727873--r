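## Accessor generics; slot access outside the package should go through these.

#' @rdname AssociationDataset-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname AssociationDataset-class
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname AssociationDataset-class
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname AssociationDataset-class
#' @export
setGeneric("nMirnas", function(x) standardGeneric("nMirnas"))

#' @rdname AssociationDataset-class
#' @export
setGeneric("nDiseases", function(x) standardGeneric("nDiseases"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelIds", function(x) standardGeneric("kernelIds"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelName", function(x) standardGeneric("kernelName"))

#' @rdname KronRLSFit-class
#' @export
setGeneric("predictedScores", function(x) standardGeneric("predictedScores"))

#' @rdname KronRLSFit-class
#' @export
setGeneric("dualCoefficients",
           function(x) standardGeneric("dualCoefficients"))

#' @rdname KernelWeights-class
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname MKLFit-class
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname RocCurve-class
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

setMethod("mirnaIds", "AssociationDataset", function(x) x@mirnaIds)
setMethod("diseaseIds", "AssociationDataset", function(x) x@diseaseIds)
setMethod("assocMatrix", "AssociationDataset", function(x) x@assoc)
setMethod("nMirnas", "AssociationDataset", function(x) length(x@mirnaIds))
setMethod("nDiseases", "AssociationDataset", function(x) length(x@diseaseIds))

setMethod("kernelIds", "SimilarityKernel", function(x) x@ids)
setMethod("kernelMatrix", "SimilarityKernel", function(x) x@matrix)
setMethod("kernelName", "SimilarityKernel", function(x) x@name)

setMethod("predictedScores", "KronRLSFit", function(x) x@F)
setMethod("dualCoefficients", "KronRLSFit", function(x) x@alpha)
setMethod("predictedScores", "MKLFit", function(x) x@fit@F)
setMethod("dualCoefficients", "MKLFit", function(x) x@fit@alpha)

setMethod("weightValues", "KernelWeights", function(x) x@values)
setMethod("objectiveTrace", "MKLFit", function(x) x@objectiveTrace)

setMethod("auc", "RocCurve", function(x) x@auc)
setMethod("auc", "CVReport", function(x) x@auc)

## show() methods --------------------------------------------------------

setMethod("show", "AssociationDataset", function(object) {
  cat(sprintf("AssociationDataset: %d miRNAs x %d diseases, %d associations\n",
              nMirnas(object), nDiseases(object), sum(object@assoc)))
})

setMethod("show", "SimilarityKernel", function(object) {
  cat(sprintf("SimilarityKernel '%s': %d x %d\n", object@name,
              length(object@ids), length(object@ids)))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG '%s': %d terms, %d edges\n", object@diseaseId,
              length(object@terms), nrow(object@edges)))
})

setMethod("show", "DAGCollection", function(object) {
  cat(sprintf("DAGCollection: %d diseases, %d distinct terms\n",
              length(object@dags), length(object@termFrequency)))
})

setMethod("show", "KronRLSFit", function(object) {
  cat(sprintf("KronRLSFit: %d x %d scores, lambda = %g\n",
              nrow(object@F), ncol(object@F), object@lam))
})

setMethod("show", "MKLFit", function(object) {
  cat(sprintf(
    "MKLFit: %d disease / %d miRNA kernels, %d cycles, objective %.6g\n",
    length(object@betaD@values), length(object@betaM@values),
    length(object@objectiveTrace) - 1L,
    object@objectiveTrace[length(object@objectiveTrace)]))
  cat("  betaD:", signif(object@betaD@values, 4), "\n")
  cat("  betaM:", signif(object@betaM@values, 4), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n", length(object@fpr),
              object@auc))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport (%s): %d held-out associations, AUC = %.4f\n",
              object@mode, nrow(object@ranks), object@auc))
  if (object@mode == "kfold" && !is.na(object@repeatsSd))
    cat(sprintf("  over repeats: %.4f +/- %.4f\n", object@repeatsMean,
                object@repeatsSd))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf(
    "SyntheticBundle: %d x %d dataset, %d disease / %d miRNA kernels\n",
    nMirnas(object@dataset), nDiseases(object@dataset),
    length(object@kernelsD), length(object@kernelsM)))
})
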