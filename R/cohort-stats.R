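#' @include AllClasses.R utils.R
NULL

#' @importFrom survival Surv survfit survdiff
NULL

#' Kaplan-Meier product-limit estimate
#'
#' Estimates `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event
#' times. Observations beyond `horizon_days` are administratively censored at
#' the horizon (truncating the display window, e.g. five years = 1826 days,
#' without excluding patients).
#'
#' @param time follow-up times in days (>= 0).
#' @param event 0 = censored, 1 = event.
#' @param horizon_days truncation horizon (default `Inf`, no truncation).
#' @return A `data.frame` of the step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with the horizon as an attribute.
#' @examples
#' kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
kmEstimate <- function(time, event, horizon_days = Inf) {
  if (!length(time)) emtStop("valueError", "empty group")
  if (any(time < 0)) emtStop("valueError", "times must be >= 0")
  if (!all(event %in% c(0, 1))) emtStop("valueError", "event must be 0/1")
  event <- ifelse(time > horizon_days, 0, event)
  time <- pmin(time, horizon_days)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "horizon_days") <- horizon_days
  out
}

#' Log-rank comparison of two or more survival groups
#'
#' Standard log-rank chi-square over the pooled distinct event times, with
#' `groups - 1` degrees of freedom. When no events occur anywhere the
#' statistic is undefined; the comparison returns `p = 1` with a flag.
#'
#' @param time,event as in [kmEstimate()].
#' @param group group label per observation (>= 2 non-empty groups).
#' @param horizon_days optional administrative-censoring horizon.
#' @return A list: `chisq`, `df`, `p`, `no_events` (flag).
#' @examples
#' logrankTest(c(1, 2, 3, 9, 10, 11), rep(1, 6), rep(c("a", "b"), each = 3))
#' @export
logrankTest <- function(time, event, group, horizon_days = Inf) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) emtStop("valueError", "need >= 2 groups")
  if (any(table(group) == 0L)) emtStop("valueError", "empty group")
  event <- ifelse(time > horizon_days, 0, event)
  time <- pmin(time, horizon_days)
  if (sum(event) == 0)
    return(list(chisq = 0, df = nlevels(group) - 1L, p = 1,
                no_events = TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       no_events = FALSE)
}

#' Correlate a driver gene with the signature genes, grouped by gene cluster
#'
#' Computes the Pearson correlation of each signature gene with the driver
#' (e.g. an EMT transcription factor such as ZEB1 or SNAI1) across samples,
#' labels every gene with its gene-cluster annotation, and tests whether the
#' correlation distributions differ between clusters with a Kruskal-Wallis
#' test (chi-square approximation with tie correction). The driver itself is
#' excluded from its own group (its self-correlation of 1 would distort the
#' comparison) and flagged.
#'
#' @param x an [ExpressionMatrix-class] (log2 scale recommended).
#' @param driver gene identifier present in `x`.
#' @param gene_clusters named vector mapping signature genes to cluster
#'   labels (e.g. `EMT-up` / `partial-EMT` / `EMT-down`).
#' @return A list: `table` (`data.frame` gene_id, r, cluster), `kw_h`,
#'   `kw_p`, `driver`, `driver_excluded` (flag).
#' @export
driverCorrelation <- function(x, driver, gene_clusters) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!driver %in% geneIds(x))
    emtStop("valueError", "driver '%s' not in matrix", driver)
  v <- exprValues(x)
  dvec <- v[driver, ]
  if (stats::sd(dvec) == 0)
    emtStop("constantItemError", "driver '%s' is constant across samples",
            driver)
  genes <- intersect(names(gene_clusters), rownames(v))
  if (!length(genes)) emtStop("valueError", "no labelled gene found in matrix")
  driverExcluded <- driver %in% genes
  genes <- setdiff(genes, driver)
  keep <- genes[apply(v[genes, , drop = FALSE], 1L, stats::sd) > 0]
  r <- as.vector(stats::cor(t(v[keep, , drop = FALSE]), dvec))
  tab <- data.frame(gene_id = keep, r = r,
                    cluster = unname(gene_clusters[keep]),
                    stringsAsFactors = FALSE)
  if (length(unique(tab$cluster)) < 2L)
    emtStop("valueError", "need >= 2 gene clusters for the Kruskal-Wallis test")
  kw <- stats::kruskal.test(tab$r, factor(tab$cluster))
  list(table = tab, kw_h = unname(kw$statistic), kw_p = kw$p.value,
       driver = driver, driver_excluded = driverExcluded)
}

#' Significance stars for a p-value
#'
#' Thresholds 0.05 / 0.01 / 0.001 / 0.0001 map to `*` .. `****`; larger
#' p-values give `"ns"`.
#'
#' @param p p-value.
#' @return A character star code.
#' @examples
#' starCode(0.004)  # "**"
#' @export
starCode <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Two-group expression comparison
#'
#' Mann-Whitney U (two-sided, normal approximation with tie correction, no
#' continuity correction) by default — robust for skewed expression values —
#' with a Welch t-test alternative. Returns the statistic, p-value and star
#' code.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param method `"wilcoxon"` or `"t"`.
#' @return A list: `statistic` (U for Wilcoxon, t otherwise), `p`, `stars`.
#' @examples
#' groupExpressionTest(c(1, 2, 3), c(10, 11, 12))
#' @export
groupExpressionTest <- function(a, b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    emtStop("valueError", "each group needs >= 2 values")
  if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    stat <- unname(wt$statistic)
  } else {
    wt <- stats::t.test(a, b)
    stat <- unname(wt$statistic)
  }
  p <- min(1, wt$p.value)
  list(statistic = stat, p = p, stars = starCode(p))
}

#' Summarise copy-number categories per group
#'
#' Accepts thresholded GISTIC-style calls in `{-2, -1, 0, 1, 2}` (negative =
#' deletion, zero = normal, positive = amplification) or ready-made category
#' labels, and reports counts and percentages per group.
#'
#' @param cnv integer calls in `-2..2` or characters in
#'   `deletion`/`normal`/`amplification`.
#' @param group group label per sample (single group when omitted).
#' @return A `data.frame` with columns `group`, `category`, `n`, `pct`;
#'   percentages sum to 100 within each group.
#' @examples
#' cnvSummary(c(-1, 0, 1, 2, 2))
#' @export
cnvSummary <- function(cnv, group = NULL) {
  if (is.null(group)) group <- rep("all", length(cnv))
  if (length(cnv) != length(group))
    emtStop("valueError", "cnv and group lengths differ")
  if (is.numeric(cnv)) {
    if (!all(cnv %in% -2:2))
      emtStop("valueError", "thresholded CNV values must lie in {-2,...,2}")
    cnv <- ifelse(cnv < 0, "deletion", ifelse(cnv == 0, "normal",
                                              "amplification"))
  } else if (!all(cnv %in% .CNV_LEVELS)) {
    emtStop("valueError", "invalid CNV category value(s)")
  }
  cnv <- factor(cnv, levels = .CNV_LEVELS)
  out <- do.call(rbind, lapply(unique(group), function(g) {
    n <- table(cnv[group == g])
    data.frame(group = g, category = names(n), n = as.integer(n),
               pct = 100 * as.integer(n) / sum(n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Score a perturbation experiment against a reference signature
#'
#' For every signature gene, asks whether its expected regulation (induction
#' for upregulated members, repression for downregulated members) is realised
#' in each condition relative to the baseline: realised means the log2 ratio
#' versus baseline exceeds `threshold` in the expected direction (default 1,
#' mirroring the 2-fold criterion the signature itself was derived with). A
#' gene whose expected direction is lost is "affected" — e.g. a knockout in
#' which most up-genes are no longer induced reports a high up-affected
#' fraction. Signature genes absent from the matrix are dropped and counted.
#'
#' @param sig a [SignatureSet-class].
#' @param x an [ExpressionMatrix-class] on a log2 scale with one column per
#'   condition.
#' @param baseline column (condition) identifier to compare against.
#' @param threshold log2-ratio threshold for calling the direction realised.
#' @return A list:
#'   * `per_gene`: `data.frame` (gene_id, direction, condition, log2_ratio,
#'     affected),
#'   * `fractions`: `data.frame` (condition, direction, n, n_affected,
#'     affected_pct),
#'   * `n_dropped`: signature genes missing from the matrix.
#' @export
signatureResponse <- function(sig, x, baseline, threshold = 1) {
  stopifnot(is(sig, "SignatureSet"), is(x, "ExpressionMatrix"))
  if (!baseline %in% sampleIds(x))
    emtStop("valueError", "baseline condition '%s' not in matrix", baseline)
  hit <- dropAbsentGenes(sig, geneIds(x))
  sigP <- hit$signature
  if (!length(sigGenes(sigP)))
    emtStop("valueError", "no signature gene present in the matrix")
  v <- exprValues(x)
  conditions <- setdiff(sampleIds(x), baseline)
  if (!length(conditions))
    emtStop("valueError", "need at least one non-baseline condition")
  genes <- sigGenes(sigP)
  dirs <- ifelse(genes %in% sigUp(sigP), "up", "down")
  perGene <- do.call(rbind, lapply(conditions, function(cond) {
    ratio <- v[genes, cond] - v[genes, baseline]
    realised <- ifelse(dirs == "up", ratio > threshold, ratio < -threshold)
    data.frame(gene_id = genes, direction = dirs, condition = cond,
               log2_ratio = unname(ratio), affected = !realised,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  fractions <- do.call(rbind, lapply(split(
    perGene, list(perGene$condition, perGene$direction), drop = TRUE),
    function(d) data.frame(condition = d$condition[1L],
                           direction = d$direction[1L], n = nrow(d),
                           n_affected = sum(d$affected),
                           affected_pct = 100 * mean(d$affected),
                           stringsAsFactors = FALSE)))
  rownames(fractions) <- NULL
  list(per_gene = perGene, fractions = fractions,
       n_dropped = length(hit$dropped))
}
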