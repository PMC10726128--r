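#' @include AllClasses.R utils.R
NULL

#' Pearson correlation distance
#'
#' `d(i, j) = 1 - r(i, j)` over the requested axis profiles: symmetric, zero
#' diagonal, range `[0, 2]` (2 = exact anti-correlation). A constant item has
#' no defined correlation and is rejected by name — z-score the matrix first
#' and drop flagged constant genes.
#'
#' @param x an [ExpressionMatrix-class].
#' @param axis `"gene"` (rows) or `"sample"` (columns).
#' @return A symmetric numeric matrix with item identifiers as dimnames.
#' @export
correlationDistance <- function(x, axis = c("gene", "sample")) {
  stopifnot(is(x, "ExpressionMatrix"))
  axis <- match.arg(axis)
  v <- if (axis == "gene") t(exprValues(x)) else exprValues(x)
  if (ncol(v) < 3L)
    emtStop("valueError", "need >= 3 %ss to compute pairwise correlation",
            axis)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    emtStop("constantItemError", "constant %s(s): %s", axis,
            paste(colnames(v)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(v)
  d[d < 0] <- 0  # numerical guard
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] producing a
#' [ClusteringOutcome-class]; cut it at any `k` with [labelsAtK()].
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param linkage `"complete"` (default), `"average"` or `"ward"`
#'   (Ward.D2).
#' @param axis which axis the items represent (bookkeeping only).
#' @param distance distance label for bookkeeping.
#' @return A [ClusteringOutcome-class].
#' @export
hcluster <- function(d, linkage = c("complete", "average", "ward"),
                     axis = c("sample", "gene"),
                     distance = c("correlation", "euclidean")) {
  linkage <- match.arg(linkage)
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  dm <- if (inherits(d, "dist")) d else stats::as.dist(d)
  if (anyNA(dm)) emtStop("valueError", "NA/NaN in distance matrix")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(dm, method = method)
  new("ClusteringOutcome", axis = axis, tree = tree, distance = distance,
      linkage = linkage)
}

## ---- stability indices (shared internal kernels) -------------------------

## Connectivity: for each item, its L nearest neighbours (by distance, self
## excluded, ties resolved by index order) contribute 1/j when the j-th
## neighbour sits in a different cluster. Lower is better.
.connectivity <- function(d, labels, L) {
  n <- nrow(d)
  penalty <- 0
  for (i in seq_len(n)) {
    o <- order(d[i, ])
    o <- o[o != i][seq_len(L)]
    penalty <- penalty + sum((labels[o] != labels[i]) / seq_len(L))
  }
  penalty
}

## Dunn index: min between-cluster distance / max within-cluster diameter.
## A singleton has diameter 0 and so never inflates the denominator.
.dunnIndex <- function(d, labels) {
  ids <- unique(labels)
  k <- length(ids)
  diam <- 0
  minInter <- Inf
  idx <- lapply(ids, function(cl) which(labels == cl))
  for (a in seq_len(k)) {
    ia <- idx[[a]]
    if (length(ia) > 1L) diam <- max(diam, max(d[ia, ia]))
    for (b in seq_len(k)) {
      if (b <= a) next
      minInter <- min(minInter, min(d[ia, idx[[b]], drop = FALSE]))
    }
  }
  if (diam == 0) return(Inf)
  minInter / diam
}

## Mean silhouette width over items; singletons contribute 0.
.meanSilhouette <- function(d, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Cluster-count stability scan
#'
#' Clusters one axis hierarchically and, for every `k` in `k_range`, scores
#' the `k`-cut partition with three stability indices: connectivity (>= 0,
#' lower is better — penalises nearest neighbours split across clusters),
#' the Dunn index (> 0, higher is better — minimum between-cluster distance
#' over maximum cluster diameter) and mean silhouette width (in `[-1, 1]`,
#' higher is better). Singleton clusters contribute a silhouette of 0 and a
#' diameter of 0, and are flagged in the returned profile.
#'
#' @param x an [ExpressionMatrix-class].
#' @param axis `"sample"` or `"gene"`.
#' @param k_range integer vector of cluster counts to scan (default 2..10).
#' @param L neighbour count for connectivity (default 10, the conventional
#'   choice in the stability-validation literature).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage linkage method, see [hcluster()].
#' @return A `data.frame` (class `StabilityProfile`) with columns `k`,
#'   `connectivity`, `dunn`, `silhouette`, `has_singleton`; the clustering
#'   outcome is attached as `attr(., "outcome")` and `L` as `attr(., "L")`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 1, 10, 11), 1,
#'   dimnames = list("g", paste0("s", 1:4))), "log2cpm")
#' stabilityScan(m, "sample", k_range = 2, L = 1, distance = "euclidean")
#' @export
stabilityScan <- function(x, axis = c("sample", "gene"), k_range = 2:10,
                          L = 10L, distance = c("correlation", "euclidean"),
                          linkage = c("complete", "average", "ward")) {
  stopifnot(is(x, "ExpressionMatrix"))
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  v <- if (axis == "sample") t(exprValues(x)) else exprValues(x)
  n <- nrow(v)
  if (n <= max(k_range))
    emtStop("valueError", "%d %ss cannot support k up to %d", n, axis,
            max(k_range))
  d <- if (distance == "correlation") {
    correlationDistance(x, axis = if (axis == "sample") "sample" else "gene")
  } else {
    as.matrix(stats::dist(v))
  }
  out <- hcluster(d, linkage = linkage, axis = axis, distance = distance)
  L <- min(as.integer(L), n - 1L)
  prof <- data.frame(k = as.integer(k_range), connectivity = NA_real_,
                     dunn = NA_real_, silhouette = NA_real_,
                     has_singleton = FALSE)
  for (r in seq_len(nrow(prof))) {
    lab <- labelsAtK(out, prof$k[r])
    prof$connectivity[r] <- .connectivity(d, lab, L)
    prof$dunn[r] <- .dunnIndex(d, lab)
    prof$silhouette[r] <- .meanSilhouette(d, lab)
    prof$has_singleton[r] <- any(tabulate(lab) == 1L)
  }
  class(prof) <- c("StabilityProfile", "data.frame")
  attr(prof, "outcome") <- out
  attr(prof, "L") <- L
  prof
}

#' Recommend a cluster count from a stability profile
#'
#' Ranks the scanned `k` values per index (connectivity ascending; Dunn and
#' silhouette descending), averages the three ranks and recommends the `k`
#' with the best (lowest) mean rank; ties go to the smaller `k` and are
#' flagged. The full rank table is always returned so the recommendation can
#' be overruled with external information (e.g. subtype separation), as done
#' when a human inspects the stratification.
#'
#' @param profile a [stabilityScan()] result.
#' @return A list: `k` (recommended), `ranks` (`data.frame` with per-metric
#'   and mean ranks), `tie` (logical).
#' @export
selectK <- function(profile) {
  stopifnot(all(c("k", "connectivity", "dunn", "silhouette") %in%
                  colnames(profile)))
  rk <- data.frame(
    k = profile$k,
    connectivity = rank(profile$connectivity, ties.method = "average"),
    dunn = rank(-profile$dunn, ties.method = "average"),
    silhouette = rank(-profile$silhouette, ties.method = "average"))
  rk$mean_rank <- rowMeans(rk[, c("connectivity", "dunn", "silhouette")])
  best <- rk$mean_rank == min(rk$mean_rank)
  list(k = min(rk$k[best]), ranks = rk, tie = sum(best) > 1L)
}

#' Annotate gene clusters by up-gene composition
#'
#' For each gene cluster, computes the fraction of its members that are
#' consensus-upregulated and labels the cluster `EMT-up` when
#' `frac_up >= tau_up`, `EMT-down` when `frac_up <= tau_down`, and
#' `partial-EMT` otherwise. The fractions are always reported alongside the
#' labels so the thresholded reading can be checked against the composition
#' (a cluster with 91% upregulated genes reads as EMT-up).
#'
#' @param labels named vector of cluster labels, one per clustered gene;
#'   every gene must belong to the signature.
#' @param sig the [SignatureSet-class] the genes came from.
#' @param tau_up,tau_down composition thresholds in `[0, 1]`.
#' @return A `data.frame` with columns `cluster`, `n_genes`, `frac_up`,
#'   `label`, plus the thresholds as attributes.
#' @examples
#' sig <- SignatureSet(up = c("a", "b", "c"), down = "d")
#' annotateGeneClusters(c(a = 1, b = 1, c = 2, d = 2), sig)
#' @export
annotateGeneClusters <- function(labels, sig, tau_up = 0.75,
                                 tau_down = 0.25) {
  stopifnot(is(sig, "SignatureSet"))
  genes <- names(labels)
  if (is.null(genes))
    emtStop("valueError", "labels must be named by gene id")
  outside <- setdiff(genes, sigGenes(sig))
  if (length(outside))
    emtStop("valueError", "clustered gene(s) not in the signature: %s",
            paste(utils::head(outside, 5L), collapse = ", "))
  cl <- sort(unique(labels))
  fracUp <- vapply(cl, function(g) {
    members <- genes[labels == g]
    if (!length(members))
      emtStop("valueError", "cluster %s has no signature genes", g)
    mean(members %in% sigUp(sig))
  }, numeric(1))
  lab <- ifelse(fracUp >= tau_up, "EMT-up",
                ifelse(fracUp <= tau_down, "EMT-down", "partial-EMT"))
  out <- data.frame(cluster = cl, n_genes = as.integer(table(labels)[as.character(cl)]),
                    frac_up = unname(fracUp), label = unname(lab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "tau_up") <- tau_up
  attr(out, "tau_down") <- tau_down
  out
}

#' Cluster-by-subtype composition table
#'
#' Cross-tabulates sample cluster labels against subtype labels and reports
#' counts plus both margins' percentages (each cluster row of `row_pct` sums
#' to 100; each subtype column of `col_pct` sums to 100 — "70% of all
#' basal-like cancers sit in cluster 5" reads off `col_pct`).
#'
#' @param labels cluster label per sample (no missing values).
#' @param subtype subtype label per sample, same length.
#' @return A list of matrices: `counts`, `row_pct`, `col_pct`.
#' @export
compositionTable <- function(labels, subtype) {
  if (length(labels) != length(subtype))
    emtStop("valueError", "labels and subtype lengths differ")
  if (anyNA(labels) || anyNA(subtype))
    emtStop("valueError", "unlabeled sample(s) present")
  counts <- table(cluster = labels, subtype = subtype)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  list(counts = counts,
       row_pct = 100 * counts / rowSums(counts),
       col_pct = 100 * sweep(counts, 2L, colSums(counts), "/"))
}
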