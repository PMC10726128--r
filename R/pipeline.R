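#' @include AllClasses.R utils.R matrix-io.R diffexp.R gsea.R clustering.R
#' @include cohort-stats.R
NULL

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

.writeManifest <- function(outDir, stage, params, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage, params = params,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  path <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}

#' Derivation workflow: paired model libraries to consensus signature
#'
#' Runs the signature-derivation arm end to end: per-model differential
#' expression on the paired epithelial/mesenchymal libraries, cross-model
#' consensus intersection, optional preranked enrichment of each model's
#' ranking against a gene-set collection, and optional overlap analysis
#' against a reference signature database. All artifacts (per-model DE TSVs,
#' signature GMT, GSEA and overlap TSVs) are written under `out_dir`
#' together with a manifest recording the parameters, seed and the MD5
#' checksum of every file, so a rerun with the same inputs is bit-identical.
#'
#' @param models named list (>= 2) of two-sample [ExpressionMatrix-class]
#'   count matrices with a `condition` column in `colData`.
#' @param out_dir output directory (created if needed).
#' @param gsea_collection optional [GeneSetCollection-class] scored against
#'   each model's ranking.
#' @param ref_collection optional [GeneSetCollection-class] of reference
#'   signatures for the overlap report.
#' @param fc,fdr_max,delta_cpm_min DE thresholds, see [callDE()].
#' @param min_set_size minimum reference-set size for [overlapAnalysis()].
#' @param gsea_min_size,gsea_max_size,n_perm GSEA parameters, see
#'   [runCollection()].
#' @param signature_name name stem for the exported `_UP`/`_DOWN` GMT sets.
#' @param seed integer seed (drives the GSEA permutation streams).
#' @return Invisibly, a list: `de` (per-model tables), `signature`,
#'   `gsea` (per-model result tables or NULL), `overlap` (or NULL),
#'   `manifest`.
#' @export
runDerivation <- function(models, out_dir, gsea_collection = NULL,
                          ref_collection = NULL, fc = 2, fdr_max = 0.05,
                          delta_cpm_min = 5, min_set_size = 50L,
                          gsea_min_size = 15L, gsea_max_size = 1000L,
                          n_perm = 1000L, signature_name = "EMT_SIGNATURE",
                          seed = 1L) {
  if (length(models) < 2L)
    emtStop("valueError", "consensus derivation needs >= 2 models, got %d",
            length(models))
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  for (nm in names(models)) {
    cond <- colData(models[[nm]])$condition
    if (is.null(cond) || !setequal(cond, c("epithelial", "mesenchymal")))
      emtStop("valueError",
              "model '%s' must carry one epithelial and one mesenchymal sample",
              nm)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  de <- lapply(names(models), function(nm) {
    tab <- callDE(models[[nm]], fc = fc, fdr_max = fdr_max,
                  delta_cpm_min = delta_cpm_min)
    files <<- c(files, .writeTsv(tab, file.path(out_dir,
                                                paste0("de_", nm, ".tsv"))))
    tab
  })
  names(de) <- names(models)

  sig <- consensusSignature(de)
  sigGmt <- GeneSetCollection(
    stats::setNames(list(sigUp(sig), sigDown(sig)),
                    paste0(signature_name, c("_UP", "_DOWN"))),
    stats::setNames(c("consensus upregulated", "consensus downregulated"),
                    paste0(signature_name, c("_UP", "_DOWN"))))
  sigPath <- file.path(out_dir, "signature.gmt")
  writeGMT(sigGmt, sigPath)
  files <- c(files, sigPath)
  if (length(attr(sig, "conflicting")))
    files <- c(files, .writeTsv(
      data.frame(gene_id = attr(sig, "conflicting")),
      file.path(out_dir, "conflicting_genes.tsv")))

  gsea <- NULL
  if (!is.null(gsea_collection)) {
    gsea <- lapply(names(models), function(nm) {
      rk <- buildRanking(de[[nm]])
      res <- runCollection(rk, gsea_collection, min_size = gsea_min_size,
                           max_size = gsea_max_size, n_perm = n_perm,
                           seed = streamSeed(seed, paste0("gsea-", nm)))
      res$model <- nm
      res
    })
    names(gsea) <- names(models)
    files <- c(files, .writeTsv(do.call(rbind, gsea),
                                file.path(out_dir, "gsea_results.tsv")))
  }

  overlap <- NULL
  if (!is.null(ref_collection)) {
    overlap <- overlapAnalysis(sig, ref_collection, min_size = min_set_size)
    files <- c(files,
               .writeTsv(overlap$per_set,
                         file.path(out_dir, "overlap_per_set.tsv")),
               .writeTsv(overlap$gene_frequency,
                         file.path(out_dir, "overlap_gene_frequency.tsv")))
  }

  params <- list(models = names(models), fc = fc, fdr_max = fdr_max,
                 delta_cpm_min = delta_cpm_min, min_set_size = min_set_size,
                 gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
                 n_perm = n_perm, seed = seed)
  manifest <- .writeManifest(out_dir, "derivation", params, files)
  invisible(list(de = de, signature = sig, gsea = gsea, overlap = overlap,
                 manifest = manifest))
}

#' Stratification workflow: signature + cohort to annotated clusters
#'
#' Runs the cohort arm end to end: restricts the cohort matrix to the
#' signature genes (aborting when fewer than `min_found_frac` of them are
#' present — a cohort missing most of the signature cannot be stratified),
#' z-scores genes, scans sample-cluster counts for stability, cuts samples at
#' the recommended (or forced) `k` and genes at `gene_k`, annotates gene
#' clusters by up-gene composition, and adds whatever the annotation
#' supports: subtype composition, Kaplan-Meier/log-rank survival by sample
#' cluster, driver-gene correlation, and CNV summaries. Artifacts and a
#' checksummed manifest go to `out_dir`.
#'
#' @param sig a [SignatureSet-class].
#' @param cohort an [ExpressionMatrix-class]; `counts` input is normalised to
#'   log2 CPM first, `cpm` is log-transformed, `log2cpm`/`zscore` used as is.
#'   Clinical columns (`subtype`, `time_days`, `event`, `cnv`) are read from
#'   `colData`.
#' @param out_dir output directory.
#' @param k_range scanned sample-cluster counts.
#' @param L connectivity neighbour count.
#' @param gene_k number of gene clusters to cut (default 3: EMT-up,
#'   partial-EMT, EMT-down).
#' @param sample_k force a sample-cluster count instead of the stability
#'   recommendation.
#' @param tau_up,tau_down annotation thresholds, see
#'   [annotateGeneClusters()].
#' @param driver optional driver gene for [driverCorrelation()].
#' @param horizon_days survival truncation horizon (default 1826 = 5 years).
#' @param min_found_frac quality gate: minimum fraction of signature genes
#'   that must be present in the cohort.
#' @param seed integer seed recorded in the manifest.
#' @return Invisibly, a list: `stability`, `selected_k`, `sample_labels`,
#'   `gene_labels`, `annotation` (gene-cluster table), `composition`,
#'   `survival` (`km` per cluster + `logrank`), `driver` correlation, `cnv`,
#'   `dropped_genes`, `manifest`.
#' @export
runStratification <- function(sig, cohort, out_dir, k_range = 2:10, L = 10L,
                              gene_k = 3L, sample_k = NULL, tau_up = 0.75,
                              tau_down = 0.25, driver = NULL,
                              horizon_days = 1826, min_found_frac = 0.5,
                              seed = 1L) {
  stopifnot(is(sig, "SignatureSet"), is(cohort, "ExpressionMatrix"))
  hit <- dropAbsentGenes(sig, geneIds(cohort))
  found <- length(sigGenes(hit$signature)) / length(sigGenes(sig))
  if (found < min_found_frac)
    emtStop("qualityGateError",
            "only %.0f%% of signature genes found in cohort (gate: %.0f%%)",
            100 * found, 100 * min_found_frac)
  sigP <- hit$signature

  x <- cohort[sigGenes(sigP), ]
  x <- switch(exprScale(cohort),
              counts = log2Plus1(toCPM(x)),
              cpm = log2Plus1(x),
              x)
  z <- rowZscore(x, quiet = TRUE)
  constant <- metadata(z)$constantGenes
  if (length(constant)) z <- z[setdiff(geneIds(z), constant), ]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  prof <- stabilityScan(z, axis = "sample", k_range = k_range, L = L)
  sel <- selectK(prof)
  k <- if (is.null(sample_k)) sel$k else as.integer(sample_k)
  files <- c(files, .writeTsv(as.data.frame(prof),
                              file.path(out_dir, "stability_profile.tsv")))

  sampleTree <- attr(prof, "outcome")
  sampleLabels <- labelsAtK(sampleTree, k)
  geneTree <- hcluster(correlationDistance(z, "gene"), axis = "gene")
  geneLabels <- labelsAtK(geneTree, gene_k)
  files <- c(files,
             .writeTsv(data.frame(sample_id = names(sampleLabels),
                                  cluster = unname(sampleLabels)),
                       file.path(out_dir, "sample_clusters.tsv")),
             .writeTsv(data.frame(gene_id = names(geneLabels),
                                  cluster = unname(geneLabels)),
                       file.path(out_dir, "gene_clusters.tsv")))

  annot <- annotateGeneClusters(geneLabels, sigP, tau_up = tau_up,
                                tau_down = tau_down)
  files <- c(files, .writeTsv(annot,
                              file.path(out_dir, "gene_cluster_annotation.tsv")))

  cd <- colData(cohort)
  composition <- NULL
  if ("subtype" %in% colnames(cd)) {
    composition <- compositionTable(unname(sampleLabels),
                                    cd$subtype[match(names(sampleLabels),
                                                     rownames(cd))])
    files <- c(files, .writeTsv(
      as.data.frame.table(composition$counts, responseName = "n"),
      file.path(out_dir, "composition.tsv")))
  }

  survivalRes <- NULL
  if (all(c("time_days", "event") %in% colnames(cd))) {
    idx <- match(names(sampleLabels), rownames(cd))
    tm <- cd$time_days[idx]; ev <- cd$event[idx]
    km <- lapply(sort(unique(sampleLabels)), function(g)
      kmEstimate(tm[sampleLabels == g], ev[sampleLabels == g],
                 horizon_days = horizon_days))
    names(km) <- paste0("cluster", sort(unique(sampleLabels)))
    lr <- logrankTest(tm, ev, sampleLabels, horizon_days = horizon_days)
    survivalRes <- list(km = km, logrank = lr)
    kmTab <- do.call(rbind, Map(function(tab, nm)
      cbind(group = nm, tab), km, names(km)))
    files <- c(files,
               .writeTsv(kmTab, file.path(out_dir, "km_curves.tsv")),
               .writeTsv(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                         file.path(out_dir, "logrank.tsv")))
  }

  driverRes <- NULL
  if (!is.null(driver)) {
    clusterLabelMap <- stats::setNames(annot$label, annot$cluster)
    geneClusterNames <- stats::setNames(
      clusterLabelMap[as.character(geneLabels)], names(geneLabels))
    driverRes <- driverCorrelation(z, driver, geneClusterNames)
    files <- c(files, .writeTsv(driverRes$table,
                                file.path(out_dir, "driver_correlation.tsv")))
  }

  cnvRes <- NULL
  if ("cnv" %in% colnames(cd)) {
    idx <- match(names(sampleLabels), rownames(cd))
    cnvRes <- cnvSummary(cd$cnv[idx], sampleLabels)
    files <- c(files, .writeTsv(cnvRes,
                                file.path(out_dir, "cnv_summary.tsv")))
  }

  params <- list(k_range = range(k_range), L = L, gene_k = gene_k,
                 selected_k = k, tau_up = tau_up, tau_down = tau_down,
                 driver = driver, horizon_days = horizon_days,
                 min_found_frac = min_found_frac, seed = seed,
                 dropped_genes = length(hit$dropped),
                 constant_genes = length(constant))
  manifest <- .writeManifest(out_dir, "stratification", params, files)
  invisible(list(stability = prof, selected_k = k,
                 sample_labels = sampleLabels, gene_labels = geneLabels,
                 annotation = annot, composition = composition,
                 survival = survivalRes, driver = driverRes, cnv = cnvRes,
                 dropped_genes = hit$dropped, manifest = manifest))
}
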