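#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

setOldClass("hclust")

.EXPR_SCALES <- c("counts", "cpm", "log2cpm", "zscore")

#' Gene-by-sample expression matrix with an explicit scale tag
#'
#' `ExpressionMatrix` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a single assay
#' (`"exprs"`) and a scale tag recording what the numbers mean: raw `counts`,
#' library-size-normalised `cpm` (counts per million), `log2cpm`
#' (log2(CPM + 1)), or per-gene `zscore`. Every downstream stage checks the tag
#' instead of guessing, so a cohort cannot silently be clustered on raw counts.
#' Sample annotation (condition, cohort, subtype, survival, CNV category)
#' travels in `colData`.
#'
#' Validity requires finite values, non-negative values for `counts`/`cpm`,
#' and unique non-missing gene and sample identifiers.
#'
#' @aliases ExpressionMatrix-class
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  sc <- metadata(object)$scale
  if (is.null(sc) || length(sc) != 1L || !sc %in% .EXPR_SCALES)
    return(sprintf("scale tag must be one of: %s",
                   paste(.EXPR_SCALES, collapse = ", ")))
  v <- assay(object, 1L)
  if (!is.numeric(v)) return("values must be numeric")
  if (any(!is.finite(v))) return("all values must be finite")
  if (sc %in% c("counts", "cpm") && any(v < 0))
    return(sprintf("values must be >= 0 on the '%s' scale", sc))
  g <- rownames(v); s <- colnames(v)
  if (is.null(g) || anyNA(g) || anyDuplicated(g))
    return("gene ids must be present and unique")
  if (is.null(s) || anyNA(s) || anyDuplicated(s))
    return("sample ids must be present and unique")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   unique row and column names.
#' @param scale one of `"counts"`, `"cpm"`, `"log2cpm"`, `"zscore"`.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   annotation, one row per column of `values` (stored as `colData`).
#'
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, scale = c("counts", "cpm", "log2cpm",
                                               "zscore"),
                             sampleData = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleData)) {
    sampleData <- DataFrame(row.names = colnames(values))
  } else {
    sampleData <- DataFrame(sampleData, row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(exprs = values),
                             colData = sampleData)
  metadata(se)$scale <- scale
  new("ExpressionMatrix", se)
}

#' Disjoint up/down gene lists forming a consensus signature
#'
#' The two member lists are disjoint by construction: a gene enters `up` only
#' if it is called upregulated in every contributing model, and symmetrically
#' for `down`; genes with conflicting directions across models are excluded at
#' consensus time. `provenance` optionally records, per gene, which models
#' contributed the call.
#'
#' @aliases SignatureSet-class
#' @export
setClass("SignatureSet",
         representation(up = "character", down = "character",
                        provenance = "list"))

setValidity("SignatureSet", function(object) {
  if (anyDuplicated(object@up)) return("duplicate genes in 'up'")
  if (anyDuplicated(object@down)) return("duplicate genes in 'down'")
  if (length(intersect(object@up, object@down)))
    return("'up' and 'down' must be disjoint")
  TRUE
})

#' Construct a SignatureSet
#'
#' @param up,down character vectors of gene identifiers (disjoint).
#' @param provenance optional named list mapping gene id to the models that
#'   called it.
#' @return A [SignatureSet-class] object.
#' @examples
#' SignatureSet(up = c("VIM", "ZEB1"), down = c("CDH1", "OCLN"))
#' @export
SignatureSet <- function(up = character(), down = character(),
                         provenance = list()) {
  new("SignatureSet", up = as.character(up), down = as.character(down),
      provenance = provenance)
}

#' Named collection of gene sets
#'
#' A thin container mirroring the GMT exchange format: unique set names, an
#' optional free-text description per set, and non-empty member lists without
#' within-set duplicates.
#'
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
      return("all sets must be named")
    if (anyDuplicated(names(s))) return("set names must be unique")
    for (nm in names(s)) {
      g <- s[[nm]]
      if (!is.character(g) || length(g) == 0L)
        return(sprintf("set '%s' must be a non-empty character vector", nm))
      if (anyDuplicated(g))
        return(sprintf("set '%s' contains duplicate genes", nm))
    }
  }
  if (length(object@description) &&
      !identical(names(object@description), names(s)))
    return("descriptions must be named like the sets")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param description optional character vector of per-set descriptions, named
#'   like `sets`; defaults to empty strings.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' @export
GeneSetCollection <- function(sets = list(), description = NULL) {
  sets <- lapply(sets, as.character)
  if (is.null(description)) {
    description <- rep("", length(sets))
    names(description) <- names(sets)
  }
  new("GeneSetCollection", sets = sets, description = description)
}

#' Genes ordered by a signed ranking score
#'
#' Holds a strictly ordered ranking (descending score; ties broken by gene
#' identifier for cross-platform determinism) as consumed by the preranked
#' enrichment machinery.
#'
#' @aliases RankedList-class
#' @export
setClass("RankedList",
         representation(gene = "character", score = "numeric"))

setValidity("RankedList", function(object) {
  if (length(object@gene) != length(object@score))
    return("gene and score lengths differ")
  if (anyDuplicated(object@gene)) return("gene ids must be unique")
  if (anyNA(object@score)) return("scores must not be NA")
  n <- length(object@score)
  if (n > 1L) {
    s <- object@score
    g <- object@gene
    bad <- s[-n] < s[-1L] |
      (s[-n] == s[-1L] & g[-n] >= g[-1L])
    if (any(bad))
      return("ranking must be ordered by descending score, ties by gene id")
  }
  TRUE
})

#' Construct a RankedList
#'
#' Sorts the input by descending score, breaking ties by gene identifier.
#'
#' @param gene character vector of unique gene ids.
#' @param score numeric scores (e.g. log2 fold changes), same length.
#' @return A [RankedList-class] object.
#' @examples
#' RankedList(c("a", "b", "c"), c(1, 3, -2))
#' @export
RankedList <- function(gene, score) {
  gene <- as.character(gene)
  o <- order(-score, gene, method = "radix")
  new("RankedList", gene = gene[o], score = as.numeric(score)[o])
}

#' Hierarchical clustering of one axis of an expression matrix
#'
#' Wraps the agglomerative merge tree for either the gene or the sample axis
#' together with the distance/linkage used to build it; flat partitions at any
#' `k` are obtained with [labelsAtK()].
#'
#' @aliases ClusteringOutcome-class
#' @export
setClass("ClusteringOutcome",
         representation(axis = "character", tree = "hclust",
                        distance = "character", linkage = "character"))

setValidity("ClusteringOutcome", function(object) {
  if (!object@axis %in% c("gene", "sample"))
    return("axis must be 'gene' or 'sample'")
  if (!object@distance %in% c("correlation", "euclidean"))
    return("distance must be 'correlation' or 'euclidean'")
  if (!object@linkage %in% c("complete", "average", "ward"))
    return("linkage must be 'complete', 'average' or 'ward'")
  TRUE
})
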