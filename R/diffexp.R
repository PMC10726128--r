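#' @include AllClasses.R utils.R normalize.R
NULL

#' Two-library proportion z-test for replicate-free count data
#'
#' Tests equality of a gene's proportion in two sequencing libraries: with
#' `p0 = (x1 + x2) / (n1 + n2)`,
#' `z = (x1/n1 - x2/n2) / sqrt(p0 (1 - p0) (1/n1 + 1/n2))` and the two-sided
#' p-value comes from the standard normal. With a single biological replicate
#' per state this proportion test on count fractions is the standard
#' replicate-free differential-expression test. `x1 = x2 = 0` carries no
#' evidence and yields `z = 0`, `p = 1` by convention. Vectorised over
#' `x1`/`x2`.
#'
#' @param x1,x2 non-negative counts (vectors of equal length).
#' @param n1,n2 positive library sizes.
#' @return A list with numeric vectors `z` and `p`.
#' @examples
#' proportionTest(30, 60, 1e6, 1e6)
#' @export
proportionTest <- function(x1, x2, n1, n2) {
  if (n1 <= 0 || n2 <= 0) emtStop("valueError", "library sizes must be > 0")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2))
    emtStop("valueError", "counts must satisfy 0 <= x <= n")
  p0 <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (x1 / n1 - x2 / n2) / se)
  p <- ifelse(se == 0, 1, 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone after sorting, capped at 1), in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    emtStop("valueError", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from one paired model
#'
#' Computes, per gene, CPM in each state, the signed log2 fold change on
#' pseudocounted CPM (`log2((cpm_mes + c) / (cpm_epi + c))`, default `c = 1`
#' so zeros stay finite), the CPM difference, the proportion-test p-value and
#' its BH-adjusted FDR. A gene is called `up` when
#' `log2FC > log2(fc)`, `fdr < fdr_max` and `delta_cpm > delta_cpm_min`
#' (mesenchymal above epithelial), symmetrically `down`; otherwise `none`.
#' Default thresholds: fold change > 2, FDR < 0.05, |ΔCPM| > 5.
#'
#' @param x an [ExpressionMatrix-class] on the `counts` scale containing the
#'   two libraries of one model.
#' @param epithelial,mesenchymal sample identifiers of the two columns; by
#'   default taken from a `condition` column in `colData(x)`.
#' @param fc fold-change threshold (linear scale).
#' @param fdr_max FDR threshold.
#' @param delta_cpm_min |CPM difference| threshold.
#' @param pseudocount CPM pseudocount for the fold change.
#' @return A `data.frame` (one row per gene, input order) with columns
#'   `gene_id`, `cpm_epithelial`, `cpm_mesenchymal`, `log2_fold_change`,
#'   `delta_cpm`, `p_value`, `fdr`, `direction`.
#' @examples
#' cnt <- matrix(c(20, 1000, 80, 1000), 2,
#'   dimnames = list(c("gA", "gB"), c("epi", "mes")))
#' callDE(ExpressionMatrix(cnt, "counts"), "epi", "mes")
#' @export
callDE <- function(x, epithelial = NULL, mesenchymal = NULL,
                   fc = 2, fdr_max = 0.05, delta_cpm_min = 5,
                   pseudocount = 1) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "counts")
    emtStop("scaleError", "callDE requires the 'counts' scale")
  if (is.null(epithelial) || is.null(mesenchymal)) {
    cond <- colData(x)$condition
    if (is.null(cond))
      emtStop("valueError",
              "no condition annotation; give epithelial/mesenchymal sample ids")
    epithelial <- sampleIds(x)[cond == "epithelial"]
    mesenchymal <- sampleIds(x)[cond == "mesenchymal"]
  }
  if (length(epithelial) != 1L || length(mesenchymal) != 1L ||
      !all(c(epithelial, mesenchymal) %in% sampleIds(x)))
    emtStop("valueError", "need exactly one epithelial and one mesenchymal sample")
  v <- exprValues(x)
  nEpi <- sum(v[, epithelial]); nMes <- sum(v[, mesenchymal])
  if (nEpi == 0 || nMes == 0)
    emtStop("zeroLibraryError", "library with zero total counts")
  cpmE <- v[, epithelial] / nEpi * 1e6
  cpmM <- v[, mesenchymal] / nMes * 1e6
  lfc <- log2((cpmM + pseudocount) / (cpmE + pseudocount))
  delta <- cpmM - cpmE
  pt <- proportionTest(v[, mesenchymal], v[, epithelial], nMes, nEpi)
  q <- bhAdjust(pt$p)
  lfcCut <- log2(fc)
  direction <- rep("none", nrow(v))
  direction[lfc > lfcCut & q < fdr_max & delta > delta_cpm_min] <- "up"
  direction[lfc < -lfcCut & q < fdr_max & delta < -delta_cpm_min] <- "down"
  data.frame(gene_id = geneIds(x), cpm_epithelial = unname(cpmE),
             cpm_mesenchymal = unname(cpmM), log2_fold_change = unname(lfc),
             delta_cpm = unname(delta), p_value = unname(pt$p),
             fdr = unname(q), direction = direction,
             stringsAsFactors = FALSE)
}

#' Intersect per-model DE calls into a consensus signature
#'
#' A gene enters the consensus `up` (`down`) list when it is called `up`
#' (`down`) in every model. Genes called in all models but with inconsistent
#' directions are excluded and reported in the `"conflicting"` attribute —
#' the Venn logic of a cross-model core admits only all-model agreement.
#'
#' @param de_tables list (>= 2) of [callDE()] results, optionally named by
#'   model.
#' @return A [SignatureSet-class]; per-gene provenance lists the contributing
#'   models and `attr(., "conflicting")` the excluded inconsistent genes.
#' @examples
#' t1 <- data.frame(gene_id = c("a", "b"), direction = c("up", "down"))
#' t2 <- data.frame(gene_id = c("a", "b"), direction = c("up", "up"))
#' sigUp(consensusSignature(list(m1 = t1, m2 = t2)))
#' @export
consensusSignature <- function(de_tables) {
  if (length(de_tables) < 2L)
    emtStop("valueError", "consensus needs >= 2 models, got %d",
            length(de_tables))
  if (is.null(names(de_tables)))
    names(de_tables) <- paste0("model", seq_along(de_tables))
  ups <- lapply(de_tables, function(d) d$gene_id[d$direction == "up"])
  downs <- lapply(de_tables, function(d) d$gene_id[d$direction == "down"])
  up <- Reduce(intersect, ups)
  down <- Reduce(intersect, downs)
  called <- Reduce(intersect, Map(function(u, d) c(u, d), ups, downs))
  conflicting <- setdiff(called, c(up, down))
  prov <- c(
    stats::setNames(rep(list(names(de_tables)), length(up)), up),
    stats::setNames(rep(list(names(de_tables)), length(down)), down))
  out <- SignatureSet(up = up, down = down, provenance = prov)
  attr(out, "conflicting") <- conflicting
  out
}

#' Overlap of a signature with a reference gene-set collection
#'
#' For every reference set `B` with at least `min_size` members, reports
#' `|Q ∩ B|` and the fraction `|Q ∩ B| / |Q|` where `Q` is the signature's
#' combined up+down gene list (normalising by the query, matching the
#' convention "x% of our signature genes were found in ..."); alternative
#' denominators (`"reference"`: `|B|`; `"jaccard"`) are available. Also
#' tallies, per query gene, how many retained references contain it.
#'
#' @param query a [SignatureSet-class].
#' @param refs a [GeneSetCollection-class].
#' @param min_size minimum reference-set size; smaller sets are disregarded.
#' @param denominator `"query"` (default), `"reference"` or `"jaccard"`.
#' @return A list with
#'   * `per_set`: `data.frame` (set, size, overlap, fraction),
#'   * `mean_fraction`: mean overlap fraction over retained sets,
#'   * `gene_frequency`: `data.frame` (gene_id, n_refs) over query genes,
#'   * `n_retained`, `n_disregarded`.
#' @examples
#' q <- SignatureSet(up = c("a", "b"), down = c("c", "d"))
#' refs <- GeneSetCollection(list(R1 = c("c", "d", "e")))
#' overlapAnalysis(q, refs, min_size = 1)$per_set
#' @export
overlapAnalysis <- function(query, refs, min_size = 50L,
                            denominator = c("query", "reference", "jaccard")) {
  stopifnot(is(query, "SignatureSet"), is(refs, "GeneSetCollection"))
  denominator <- match.arg(denominator)
  Q <- sigGenes(query)
  if (!length(Q)) emtStop("valueError", "empty query signature")
  sets <- geneSets(refs)
  keep <- lengths(sets) >= min_size
  retained <- sets[keep]
  perSet <- data.frame(
    set = names(retained),
    size = unname(lengths(retained)),
    overlap = vapply(retained, function(b) length(intersect(Q, b)),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  perSet$fraction <- switch(denominator,
    query = perSet$overlap / length(Q),
    reference = perSet$overlap / perSet$size,
    jaccard = perSet$overlap /
      vapply(retained, function(b) length(union(Q, b)), integer(1)))
  freq <- vapply(Q, function(g)
    sum(vapply(retained, function(b) g %in% b, logical(1))), integer(1))
  list(per_set = perSet,
       mean_fraction = if (nrow(perSet)) mean(perSet$fraction) else NA_real_,
       gene_frequency = data.frame(gene_id = Q, n_refs = unname(freq),
                                   stringsAsFactors = FALSE),
       n_retained = sum(keep), n_disregarded = sum(!keep))
}
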