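#' @include AllClasses.R
NULL

#' Accessors for ExpressionMatrix
#'
#' `exprValues` returns the numeric gene-by-sample matrix, `exprScale` the
#' scale tag, `geneIds`/`sampleIds` the row/column identifiers.
#'
#' @param x an [ExpressionMatrix-class].
#' @return `exprValues`: numeric matrix; `exprScale`: length-1 character;
#'   `geneIds`, `sampleIds`: character vectors.
#' @name ExpressionMatrix-accessors
#' @examples
#' m <- ExpressionMatrix(matrix(1:4, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "counts")
#' exprScale(m)
#' geneIds(m)
NULL

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Accessors for SignatureSet
#'
#' `sigUp`/`sigDown` return the up-/downregulated member genes, `sigGenes`
#' their union, and `sigProvenance` the per-gene contributing-model records.
#'
#' @param x a [SignatureSet-class].
#' @return Character vectors (`sigUp`, `sigDown`, `sigGenes`) or a list
#'   (`sigProvenance`).
#' @name SignatureSet-accessors
#' @examples
#' s <- SignatureSet(up = "VIM", down = "CDH1")
#' sigGenes(s)
NULL

#' @rdname SignatureSet-accessors
#' @export
setGeneric("sigUp", function(x) standardGeneric("sigUp"))

#' @rdname SignatureSet-accessors
#' @export
setGeneric("sigDown", function(x) standardGeneric("sigDown"))

#' @rdname SignatureSet-accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))

#' @rdname SignatureSet-accessors
#' @export
setGeneric("sigProvenance", function(x) standardGeneric("sigProvenance"))

#' Accessor for GeneSetCollection
#'
#' @param x a [GeneSetCollection-class].
#' @return `geneSets`: the named list of member vectors; `setDescriptions`:
#'   named character vector of descriptions.
#' @name GeneSetCollection-accessors
NULL

#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' Accessors for RankedList
#'
#' @param x a [RankedList-class].
#' @return `rankedGenes`: ordered character vector; `rankedScores`: numeric
#'   scores in the same order.
#' @name RankedList-accessors
NULL

#' @rdname RankedList-accessors
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname RankedList-accessors
#' @export
setGeneric("rankedScores", function(x) standardGeneric("rankedScores"))

#' Flat partition from a clustering outcome
#'
#' Cuts the stored merge tree into `k` clusters.
#'
#' @param x a [ClusteringOutcome-class].
#' @param k integer number of clusters (1 <= k <= number of items).
#' @return Named integer vector of cluster labels (1..k), one per item.
#' @export
setGeneric("labelsAtK", function(x, k) standardGeneric("labelsAtK"))
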