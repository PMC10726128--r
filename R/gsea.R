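#' @include AllClasses.R utils.R
NULL

#' Build a preranked gene list from a differential-expression table
#'
#' Keeps the genes with raw `p_value < p_cut` and orders them by descending
#' log2 fold change (ties broken by gene identifier), the convention used
#' when feeding per-model DE results into preranked enrichment.
#'
#' @param de a [callDE()] table (needs `gene_id`, `log2_fold_change`,
#'   `p_value`).
#' @param p_cut raw p-value cutoff.
#' @return A [RankedList-class].
#' @examples
#' de <- data.frame(gene_id = c("a", "b", "c"),
#'                  log2_fold_change = c(2, -1, 3),
#'                  p_value = c(0.01, 0.01, 0.5))
#' rankedGenes(buildRanking(de))
#' @export
buildRanking <- function(de, p_cut = 0.05) {
  keep <- de$p_value < p_cut
  if (!any(keep))
    emtStop("valueError", "no gene passes p < %g", p_cut)
  RankedList(de$gene_id[keep], de$log2_fold_change[keep])
}

#' Signal-to-noise ranking across labelled samples
#'
#' Ranks genes by `(mean_mes - mean_epi) / (sd_mes + sd_epi)` across all
#' samples labelled by condition, with the usual variance floor (each class SD
#' is raised to at least 0.2 x |class mean|, or 0.2 when the mean is 0) so
#' near-constant genes do not explode. This supports a combined multi-model
#' analysis: with only a few samples per class a phenotype-permutation null is
#' degenerate, so the combined mode ranks genes here and then scores them with
#' the preranked machinery and its gene-permutation null.
#'
#' @param x an [ExpressionMatrix-class] (typically `log2cpm`) whose `colData`
#'   has a `condition` column, or pass `condition` explicitly.
#' @param condition optional character vector (`"epithelial"`/`"mesenchymal"`)
#'   per sample.
#' @return A [RankedList-class] over all genes.
#' @export
rankingSignalToNoise <- function(x, condition = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (is.null(condition)) condition <- colData(x)$condition
  if (is.null(condition) || length(condition) != ncol(x))
    emtStop("valueError", "need a condition label per sample")
  v <- exprValues(x)
  grpStats <- function(g) {
    sub <- v[, condition == g, drop = FALSE]
    if (ncol(sub) < 2L)
      emtStop("valueError", "signal-to-noise needs >= 2 samples per class")
    mu <- rowMeans(sub)
    sd <- apply(sub, 1L, stats::sd)
    floor <- ifelse(mu == 0, 0.2, 0.2 * abs(mu))
    list(mu = mu, sd = pmax(sd, floor))
  }
  mes <- grpStats("mesenchymal"); epi <- grpStats("epithelial")
  RankedList(geneIds(x), (mes$mu - epi$mu) / (mes$sd + epi$sd))
}

## Core running-sum extremum from hit positions only (O(m) given sorted
## positions). Between hits the running sum decreases linearly, so the maximum
## can only occur at a hit and the minimum just before one.
.esCore <- function(N, hitPos, hitW) {
  m <- length(hitPos)
  Nm <- N - m
  NR <- sum(hitW)
  if (NR == 0) hitW <- rep(1, m) else hitW <- hitW / NR
  H <- cumsum(hitW)
  if (NR == 0) H <- H / m
  j <- seq_len(m)
  candMax <- H - (hitPos - j) / Nm
  candMin <- c(0, H[-m]) - (hitPos - j) / Nm  # value just before hit j
  iMax <- which.max(candMax); iMin <- which.min(candMin)
  ## sign convention: when the positive and negative excursions tie in
  ## magnitude (within 1e-12), report the positive one
  if (candMax[iMax] >= -candMin[iMin] - 1e-12) {
    list(es = candMax[iMax], extreme = hitPos[iMax], positive = TRUE)
  } else {
    list(es = candMin[iMin], extreme = hitPos[iMin] - 1L, positive = FALSE)
  }
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranking from top to bottom, incrementing by `|score|^weight`
#' (normalised over the set's members) at each set gene and decrementing by
#' `1/(N - m)` at each non-member; the enrichment score is the running-sum
#' value of maximum magnitude (ties resolved toward the positive extremum).
#' `weight = 1` is the classic weighted statistic; `weight = 0` reduces to a
#' Kolmogorov-Smirnov statistic on hit positions. The leading edge contains
#' the member genes at or before the extremum for a positive score, and after
#' it for a negative one.
#'
#' @param ranking a [RankedList-class].
#' @param set character vector of gene identifiers; members outside the
#'   ranking are ignored, but the restricted set must be non-empty and must
#'   not cover the whole ranking.
#' @param weight exponent on |score| for hit increments.
#' @return A list: `es`, `running_sum` (length-N numeric), `leading_edge`
#'   (character), `extreme_rank`.
#' @examples
#' r <- RankedList(letters[1:5], c(5, 4, 3, 2, 1))
#' enrichmentScore(r, c("a", "c"))$es  # 2/3
#' @export
enrichmentScore <- function(ranking, set, weight = 1) {
  stopifnot(is(ranking, "RankedList"))
  genes <- rankedGenes(ranking)
  N <- length(genes)
  hit <- genes %in% set
  m <- sum(hit)
  if (m == 0L) emtStop("valueError", "set has no genes in the ranking")
  if (m == N) emtStop("valueError",
                      "set covers the whole ranking; misses undefined")
  absw <- abs(rankedScores(ranking))^weight
  hitPos <- which(hit)
  core <- .esCore(N, hitPos, absw[hitPos])
  NR <- sum(absw[hitPos])
  inc <- if (NR == 0) rep(1 / m, N) * hit else (absw / NR) * hit
  rs <- cumsum(inc - (!hit) / (N - m))
  leading <- if (core$positive) genes[hitPos[hitPos <= core$extreme]]
             else genes[hitPos[hitPos > core$extreme]]
  list(es = core$es, running_sum = rs, leading_edge = leading,
       extreme_rank = core$extreme)
}

#' Gene-permutation null for one gene set
#'
#' Draws `n_perm` random gene sets of the observed (restricted) size from the
#' ranking, recomputes the enrichment score for each, and reports the
#' normalised score `nes = es / mean(|null ES| of matching sign)` and the
#' nominal p-value (fraction of matching-sign null scores at least as
#' extreme). When no null score matches the observed sign, `p` is reported at
#' the `1/n_perm` resolution limit and flagged. Deterministic for a fixed
#' seed.
#'
#' @param ranking a [RankedList-class].
#' @param set character vector of member genes.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight hit-increment exponent, as in [enrichmentScore()].
#' @return A list: `es`, `nes`, `p_nominal`, `leading_edge`, `size`,
#'   `n_perm`, `seed`, `at_resolution_limit` (logical flag), and the `null_es`
#'   vector.
#' @export
permutationNull <- function(ranking, set, n_perm = 1000L, seed = 1L,
                            weight = 1) {
  if (n_perm < 100L) emtStop("valueError", "n_perm must be >= 100")
  obs <- enrichmentScore(ranking, set, weight)
  genes <- rankedGenes(ranking)
  N <- length(genes)
  m <- sum(genes %in% set)
  absw <- abs(rankedScores(ranking))^weight
  nullEs <- withStream(seed, "gsea-permutation",
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, m))
      .esCore(N, pos, absw[pos])$es
    }, numeric(1)))
  same <- if (obs$es >= 0) nullEs[nullEs >= 0] else nullEs[nullEs < 0]
  flag <- length(same) == 0L
  if (flag) {
    nes <- NA_real_
    p <- 1 / n_perm
  } else {
    nes <- obs$es / mean(abs(same))
    p <- mean(abs(same) >= abs(obs$es))
    if (p == 0) {
      p <- 1 / n_perm
      flag <- TRUE
    }
  }
  list(es = obs$es, nes = nes, p_nominal = p,
       leading_edge = obs$leading_edge, size = m, n_perm = n_perm,
       seed = seed, at_resolution_limit = flag, null_es = nullEs)
}

#' Score a gene-set collection against a ranking
#'
#' Restricts every set to the ranked universe, excludes sets outside
#' `[min_size, max_size]` (reporting why), scores the rest with
#' [permutationNull()] (each set drawing its own deterministic permutation
#' stream from `seed`), and attaches FDR q-values computed by sign-stratified
#' pooling of the null NES distribution: for a positive set,
#' `q = Pr(null NES >= nes | null NES >= 0) / Pr(obs NES >= nes | obs NES >= 0)`
#' capped at 1, symmetrically for negative sets.
#'
#' @param ranking a [RankedList-class].
#' @param collection a [GeneSetCollection-class].
#' @param min_size,max_size inclusive size bounds after restriction to the
#'   ranked universe.
#' @param n_perm,seed,weight passed to [permutationNull()].
#' @return A `data.frame` sorted by decreasing NES with columns `set`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `at_resolution_limit`,
#'   `leading_edge` (semicolon-collapsed); excluded sets are in
#'   `attr(., "excluded")` (`data.frame` of set, size, reason).
#' @export
runCollection <- function(ranking, collection, min_size = 15L,
                          max_size = 1000L, n_perm = 1000L, seed = 1L,
                          weight = 1) {
  stopifnot(is(ranking, "RankedList"), is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  if (!length(sets)) emtStop("valueError", "empty collection")
  universe <- rankedGenes(ranking)
  restricted <- lapply(sets, intersect, universe)
  size <- lengths(restricted)
  reason <- rep(NA_character_, length(sets))
  reason[size == 0L] <- "no overlap with ranked universe"
  reason[size > 0L & size < min_size] <- sprintf("size < %d", min_size)
  reason[size > max_size] <- sprintf("size > %d", max_size)
  reason[size == length(universe)] <- "covers the whole ranked universe"
  excluded <- data.frame(set = names(sets)[!is.na(reason)],
                         size = unname(size[!is.na(reason)]),
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- names(sets)[is.na(reason)]
  if (!length(keep))
    emtStop("valueError", "all %d sets excluded by the size filter",
            length(sets))
  res <- lapply(keep, function(nm)
    permutationNull(ranking, restricted[[nm]], n_perm = n_perm,
                    seed = streamSeed(seed, nm), weight = weight))
  names(res) <- keep
  obsNes <- vapply(res, `[[`, numeric(1), "nes")
  ## pooled null NES: each set's null ES normalised by that set's
  ## matching-sign mean |null ES|
  nullNes <- unlist(lapply(res, function(r) {
    ne <- r$null_es
    posMean <- mean(abs(ne[ne >= 0]))
    negMean <- mean(abs(ne[ne < 0]))
    out <- ifelse(ne >= 0, ne / posMean, ne / negMean)
    out[is.finite(out)]
  }), use.names = FALSE)
  fdr <- vapply(keep, function(nm) {
    nes <- res[[nm]]$nes
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(nullNes[nullNes >= 0] >= nes)
      den <- mean(obsNes[!is.na(obsNes) & obsNes >= 0] >= nes)
    } else {
      num <- mean(nullNes[nullNes < 0] <= nes)
      den <- mean(obsNes[!is.na(obsNes) & obsNes < 0] <= nes)
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
  out <- data.frame(
    set = keep, size = unname(size[keep]),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = obsNes, p_nominal = vapply(res, `[[`, numeric(1), "p_nominal"),
    fdr_q = fdr,
    at_resolution_limit = vapply(res, `[[`, logical(1),
                                 "at_resolution_limit"),
    leading_edge = vapply(res, function(r)
      paste(r$leading_edge, collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$nes, out$set), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
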