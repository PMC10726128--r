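#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ExpressionMatrix-accessors
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, 1L))

#' @rdname ExpressionMatrix-accessors
setMethod("exprScale", "ExpressionMatrix", function(x) metadata(x)$scale)

#' @rdname ExpressionMatrix-accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix-accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object), ncol(object), exprScale(object)))
  if (ncol(colData(object)))
    cat("sample annotation:", paste(colnames(colData(object)),
                                    collapse = ", "), "\n")
})

#' @rdname SignatureSet-accessors
setMethod("sigUp", "SignatureSet", function(x) x@up)

#' @rdname SignatureSet-accessors
setMethod("sigDown", "SignatureSet", function(x) x@down)

#' @rdname SignatureSet-accessors
setMethod("sigGenes", "SignatureSet", function(x) c(x@up, x@down))

#' @rdname SignatureSet-accessors
setMethod("sigProvenance", "SignatureSet", function(x) x@provenance)

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d up + %d down = %d genes\n",
              length(object@up), length(object@down),
              length(object@up) + length(object@down)))
})

#' @rdname GeneSetCollection-accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-accessors
setMethod("setDescriptions", "GeneSetCollection", function(x) x@description)

#' @describeIn GeneSetCollection-accessors number of sets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-accessors set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("GeneSetCollection: %d sets", length(object@sets)))
  if (length(sz)) cat(sprintf(" (sizes %d..%d)", min(sz), max(sz)))
  cat("\n")
})

#' @rdname RankedList-accessors
setMethod("rankedGenes", "RankedList", function(x) x@gene)

#' @rdname RankedList-accessors
setMethod("rankedScores", "RankedList", function(x) x@score)

#' @describeIn RankedList-accessors number of ranked genes.
#' @export
setMethod("length", "RankedList", function(x) length(x@gene))

setMethod("show", "RankedList", function(object) {
  cat(sprintf("RankedList: %d genes, scores %.4g .. %.4g\n",
              length(object@gene),
              if (length(object@score)) object@score[1L] else NA,
              if (length(object@score)) object@score[length(object@score)]
              else NA))
})

#' @rdname labelsAtK
#' @aliases labelsAtK,ClusteringOutcome-method
setMethod("labelsAtK", "ClusteringOutcome", function(x, k) {
  n <- length(x@tree$order)
  if (k < 1L || k > n)
    stop("k must be between 1 and the number of clustered items (", n, ")")
  stats::cutree(x@tree, k = k)
})

setMethod("show", "ClusteringOutcome", function(object) {
  cat(sprintf(
    "ClusteringOutcome: %d %ss, %s distance, %s linkage\n",
    length(object@tree$order), object@axis, object@distance, object@linkage))
})
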