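#' @include AllClasses.R
NULL

#' Counts-per-million normalisation
#'
#' Divides each sample (column) by its library size and multiplies by 1e6, so
#' every column sums to exactly one million. Input must be on the `counts`
#' scale; a sample with zero total counts is an error (its CPM would be
#' undefined).
#'
#' @param x an [ExpressionMatrix-class] on the `counts` scale.
#' @return An [ExpressionMatrix-class] on the `cpm` scale (colData preserved).
#' @examples
#' m <- ExpressionMatrix(matrix(c(10, 1999990, 5, 999995), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "counts")
#' exprValues(toCPM(m))["g1", ]
#' @export
toCPM <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "counts")
    emtStop("scaleError", "toCPM requires the 'counts' scale, got '%s'",
            exprScale(x))
  v <- exprValues(x)
  lib <- colSums(v)
  if (any(lib == 0))
    emtStop("zeroLibraryError", "sample(s) with zero total counts: %s",
            paste(colnames(v)[lib == 0], collapse = ", "))
  out <- sweep(v, 2L, lib, "/") * 1e6
  ExpressionMatrix(out, "cpm", sampleData = colData(x))
}

#' log2(CPM + 1) transform
#'
#' Applies `log2(value + 1)` elementwise: monotone, and 0 maps to 0. Input
#' must be on the `cpm` scale with no negative values.
#'
#' @param x an [ExpressionMatrix-class] on the `cpm` scale.
#' @return An [ExpressionMatrix-class] on the `log2cpm` scale.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 1, 7, 3), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "cpm")
#' exprValues(log2Plus1(m))
#' @export
log2Plus1 <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "cpm")
    emtStop("scaleError", "log2Plus1 requires the 'cpm' scale, got '%s'",
            exprScale(x))
  v <- exprValues(x)
  if (any(v < 0)) emtStop("valueError", "negative CPM value encountered")
  ExpressionMatrix(log2(v + 1), "log2cpm", sampleData = colData(x))
}

#' Per-gene z-score normalisation
#'
#' Centres and scales every row to mean 0 and sample (n-1 denominator)
#' standard deviation 1, as done before hierarchical clustering so that
#' absolute expression level does not dominate the distance structure. Rows
#' with zero variance cannot be scaled; they are set to all-zero and their
#' identifiers reported via a message and the `"constantGenes"` attribute of
#' the result's metadata.
#'
#' @param x an [ExpressionMatrix-class] with at least 2 samples (any scale).
#' @param quiet suppress the constant-row message.
#' @return An [ExpressionMatrix-class] on the `zscore` scale; constant-row ids
#'   in `metadata(.)$constantGenes`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 5, 2, 5, 3, 5), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), "log2cpm")
#' exprValues(rowZscore(m))
#' @export
rowZscore <- function(x, quiet = FALSE) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (ncol(v) < 2L)
    emtStop("valueError", "z-scoring needs >= 2 samples, got %d", ncol(v))
  mu <- rowMeans(v)
  centred <- v - mu
  sd <- sqrt(rowSums(centred^2) / (ncol(v) - 1L))
  constant <- sd == 0
  sd[constant] <- 1  # rows already all-zero after centring
  out <- centred / sd
  out[constant, ] <- 0
  res <- ExpressionMatrix(out, "zscore", sampleData = colData(x))
  metadata(res)$constantGenes <- rownames(v)[constant]
  if (any(constant) && !quiet)
    message(sum(constant), " constant gene(s) set to zero: ",
            paste(utils::head(rownames(v)[constant], 5L), collapse = ", "),
            if (sum(constant) > 5L) ", ..." else "")
  res
}
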