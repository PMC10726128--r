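#' @include AllClasses.R utils.R
NULL

## All generators draw from named per-component RNG streams derived from the
## single config seed (see withStream), so outputs are bit-identical for a
## fixed config and adding a generator never perturbs existing draws.

#' Configuration for the paired EMT-model library generator
#'
#' Describes a panel of cell-line EMT models, each sequenced as one epithelial
#' and one mesenchymal library (single biological replicate per state), with a
#' planted consensus core of up-/downregulated genes shared by all models plus
#' model-specific differential genes.
#'
#' @param n_genes number of genes.
#' @param n_models number of paired models.
#' @param core_up,core_down size of the planted consensus core (up / down in
#'   mesenchymal vs epithelial).
#' @param model_specific_up,model_specific_down additional planted genes per
#'   model, unique to that model.
#' @param lfc_range bounds on |log2 fold change| drawn uniformly for planted
#'   genes; the lower bound should exceed 1 for the planted effect to clear a
#'   2-fold filter.
#' @param library_size sequencing depth (reads) of every library.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters for per-gene
#'   baseline abundance (relative; rescaled so expected CPM sums to 1e6).
#' @param min_planted_cpm planted genes are drawn from genes whose baseline
#'   expected CPM is at least this value; signature genes are robustly
#'   expressed genes, and an effect planted at the detection floor is not
#'   recoverable at single-replicate depth.
#' @param seed integer seed driving all streams.
#' @return A validated config (classed list) for [simulateModels()].
#' @export
modelSimConfig <- function(n_genes = 12000L, n_models = 3L,
                           core_up = 134L, core_down = 131L,
                           model_specific_up = 800L,
                           model_specific_down = 800L,
                           lfc_range = c(1.5, 4.0),
                           library_size = 2e6,
                           baseline_log_mean = 4.0, baseline_log_sd = 1.2,
                           min_planted_cpm = 20, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_models = as.integer(n_models),
              core_up = as.integer(core_up), core_down = as.integer(core_down),
              model_specific_up = as.integer(model_specific_up),
              model_specific_down = as.integer(model_specific_down),
              lfc_range = as.numeric(lfc_range),
              library_size = as.numeric(library_size),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              min_planted_cpm = min_planted_cpm, seed = as.integer(seed))
  if (cfg$n_models < 1L) emtStop("configError", "n_models must be >= 1")
  if (length(cfg$lfc_range) != 2L || any(cfg$lfc_range < 0) ||
      cfg$lfc_range[1] > cfg$lfc_range[2])
    emtStop("configError", "lfc_range must be 0 <= low <= high")
  budget <- cfg$core_up + cfg$core_down +
    cfg$n_models * (cfg$model_specific_up + cfg$model_specific_down)
  if (budget > cfg$n_genes)
    emtStop("configError",
            "planted gene budget (%d) exceeds n_genes (%d)", budget,
            cfg$n_genes)
  if (cfg$library_size <= 0)
    emtStop("configError", "library_size must be > 0")
  class(cfg) <- "ModelSimConfig"
  cfg
}

#' Simulate paired epithelial/mesenchymal RNA-seq libraries
#'
#' Per-gene baseline abundance is log-normal (rescaled to CPM). For each
#' model, the mesenchymal expectation of a planted gene is multiplied by
#' `2^(+lfc)` (up) or `2^(-lfc)` (down) — core genes share one fold change
#' across models, model-specific genes draw their own — after which the
#' mesenchymal expectations are renormalised to one million (CPM is
#' compositional). Counts are Poisson at the configured library size: with one
#' library per state no within-condition dispersion is observable, which
#' matches the proportion-test model used downstream.
#'
#' @param cfg a [modelSimConfig()].
#' @return A list with elements
#'   * `models`: named list of two-sample [ExpressionMatrix-class] objects on
#'     the `counts` scale (`<model>_epithelial`, `<model>_mesenchymal`;
#'     condition and model in `colData`),
#'   * `truth`: planted truth with `core_up`, `core_down`, `per_model`
#'     (list of `up`/`down` gene vectors per model, core included) and
#'     `baseline_cpm`.
#' @examples
#' sim <- simulateModels(modelSimConfig(n_genes = 500, core_up = 10,
#'   core_down = 10, model_specific_up = 20, model_specific_down = 20,
#'   library_size = 1e5, seed = 7))
#' sim$models[[1]]
#' length(sim$truth$core_up)
#' @export
simulateModels <- function(cfg) {
  stopifnot(inherits(cfg, "ModelSimConfig"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  base <- withStream(cfg$seed, "baseline",
                     stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean,
                                   cfg$baseline_log_sd))
  base <- base / sum(base) * 1e6  # expected CPM
  names(base) <- genes

  eligible <- which(base >= cfg$min_planted_cpm)
  nPlant <- cfg$core_up + cfg$core_down +
    cfg$n_models * (cfg$model_specific_up + cfg$model_specific_down)
  if (length(eligible) < nPlant)
    emtStop("configError",
            "only %d genes reach min_planted_cpm = %g; %d planted genes requested",
            length(eligible), cfg$min_planted_cpm, nPlant)

  modelNames <- paste0("model", seq_len(cfg$n_models))
  plan <- withStream(cfg$seed, "planting", {
    pool <- eligible[sample.int(length(eligible), nPlant)]
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    coreUp <- take(cfg$core_up)
    coreDown <- take(cfg$core_down)
    spec <- lapply(modelNames, function(m)
      list(up = take(cfg$model_specific_up),
           down = take(cfg$model_specific_down)))
    names(spec) <- modelNames
    list(coreUp = coreUp, coreDown = coreDown, spec = spec)
  })

  drawLfc <- function(n) {
    if (cfg$lfc_range[1] == cfg$lfc_range[2])
      rep(cfg$lfc_range[1], n)
    else stats::runif(n, cfg$lfc_range[1], cfg$lfc_range[2])
  }
  coreLfc <- withStream(cfg$seed, "lfc-core",
                        c(drawLfc(cfg$core_up), -drawLfc(cfg$core_down)))

  models <- vector("list", cfg$n_models)
  names(models) <- modelNames
  perModel <- vector("list", cfg$n_models)
  names(perModel) <- modelNames
  for (m in modelNames) {
    specLfc <- withStream(cfg$seed, paste0("lfc-", m),
                          c(drawLfc(cfg$model_specific_up),
                            -drawLfc(cfg$model_specific_down)))
    delta <- numeric(cfg$n_genes)
    delta[c(plan$coreUp, plan$coreDown)] <- coreLfc
    delta[c(plan$spec[[m]]$up, plan$spec[[m]]$down)] <- specLfc
    ## Mass-symmetric planting: a planted gene sits at baseline in its low
    ## state and is elevated by 2^|lfc| in its high state (mesenchymal for
    ## up genes, epithelial for down genes). Both libraries then gain
    ## comparable transcriptional mass, so the compositional CPM
    ## renormalisation leaves unplanted genes unbiased — as in a balanced
    ## up/down differential design.
    epiCpm <- base * 2^pmax(-delta, 0)
    mesCpm <- base * 2^pmax(delta, 0)
    epiCpm <- epiCpm / sum(epiCpm) * 1e6
    mesCpm <- mesCpm / sum(mesCpm) * 1e6
    counts <- withStream(cfg$seed, paste0("counts-", m), {
      cbind(stats::rpois(cfg$n_genes, epiCpm / 1e6 * cfg$library_size),
            stats::rpois(cfg$n_genes, mesCpm / 1e6 * cfg$library_size))
    })
    dimnames(counts) <- list(genes, paste0(m, c("_epithelial",
                                                "_mesenchymal")))
    models[[m]] <- ExpressionMatrix(
      counts, "counts",
      sampleData = data.frame(condition = c("epithelial", "mesenchymal"),
                              model = m))
    perModel[[m]] <- list(up = genes[c(plan$coreUp, plan$spec[[m]]$up)],
                          down = genes[c(plan$coreDown, plan$spec[[m]]$down)])
  }

  truth <- list(core_up = genes[plan$coreUp], core_down = genes[plan$coreDown],
                per_model = perModel, baseline_cpm = base)
  list(models = models, truth = truth)
}

.SUBTYPES <- c("basal-like", "luminal A", "luminal B", "HER2-enriched",
               "normal-like")
.CNV_LEVELS <- c("deletion", "normal", "amplification")

.defaultBlockMeans <- function(k) {
  patterns <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                    c(-2, 0, 0), c(0, -2, 0), c(0, 0, -2))
  if (k > nrow(patterns))
    patterns <- patterns[rep(seq_len(nrow(patterns)), length.out = k), ]
  m <- patterns[seq_len(k), , drop = FALSE]
  dimnames(m) <- list(NULL, c("EMT-up", "partial-EMT", "EMT-down"))
  m
}

.defaultSubtypeMix <- function(k) {
  mix <- rbind(c(0.30, 0.40, 0.05, 0.10, 0.15),
               c(0.70, 0.10, 0.05, 0.10, 0.05),
               c(0.02, 0.35, 0.35, 0.23, 0.05),
               c(0.10, 0.55, 0.15, 0.10, 0.10),
               c(0.15, 0.45, 0.15, 0.10, 0.15),
               c(0.05, 0.40, 0.30, 0.20, 0.05))
  mix <- mix[rep(seq_len(nrow(mix)), length.out = k), , drop = FALSE]
  colnames(mix) <- .SUBTYPES
  mix
}

.defaultCnvProbs <- function(k) {
  p <- rbind(c(0.05, 0.10, 0.85),
             c(0.03, 0.07, 0.90),
             c(0.15, 0.55, 0.30),
             c(0.15, 0.55, 0.30),
             c(0.15, 0.55, 0.30),
             c(0.15, 0.55, 0.30))
  p <- p[rep(seq_len(nrow(p)), length.out = k), , drop = FALSE]
  colnames(p) <- .CNV_LEVELS
  p
}

#' Configuration for the block-structured tumour-cohort generator
#'
#' Emulates an expression cohort restricted to signature genes: genes fall
#' into three blocks (EMT-up / partial-EMT / EMT-down), samples into
#' `n_sample_clusters` transcriptional states, and expression on the log2
#' scale is the state-by-block mean shift plus Gaussian noise. Each sample
#' cluster carries its own subtype mixture, exponential event hazard and CNV
#' category probabilities.
#'
#' Defaults plant six mutually non-nested states (amplitude-2 shifts on single
#' blocks) with one basal-like-dominated, partial-EMT-high state, echoing the
#' shape of published breast-cancer stratifications.
#'
#' @param n_samples cohort size.
#' @param gene_blocks named integer vector of block sizes
#'   (`EMT-up`, `partial-EMT`, `EMT-down`).
#' @param n_sample_clusters number of planted sample clusters.
#' @param block_mean_matrix `n_sample_clusters` x 3 matrix of log2 mean
#'   shifts (columns ordered like `gene_blocks`).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param subtype_mixture `n_sample_clusters` x 5 row-stochastic matrix over
#'   PAM50-style subtypes.
#' @param hazard_per_group exponential event rate per day, one per cluster.
#' @param censor_max upper bound (days) of the uniform administrative
#'   censoring time.
#' @param cnv_probs `n_sample_clusters` x 3 row-stochastic matrix over
#'   deletion/normal/amplification.
#' @param seed integer seed.
#' @return A validated config (classed list) for [simulateCohort()].
#' @export
cohortSimConfig <- function(n_samples = 1000L,
                            gene_blocks = c("EMT-up" = 91L,
                                            "partial-EMT" = 86L,
                                            "EMT-down" = 88L),
                            n_sample_clusters = 6L,
                            block_mean_matrix = NULL,
                            noise_sd = 0.5,
                            subtype_mixture = NULL,
                            hazard_per_group = NULL,
                            censor_max = 3650,
                            cnv_probs = NULL,
                            seed = 1L) {
  k <- as.integer(n_sample_clusters)
  if (is.null(block_mean_matrix)) block_mean_matrix <- .defaultBlockMeans(k)
  if (is.null(subtype_mixture)) subtype_mixture <- .defaultSubtypeMix(k)
  if (is.null(hazard_per_group))
    hazard_per_group <- c(4e-4, 8e-4, 2e-4, 3e-4, 3e-4,
                          2.5e-4)[rep_len(seq_len(6L), k)]
  if (is.null(cnv_probs)) cnv_probs <- .defaultCnvProbs(k)
  cfg <- list(n_samples = as.integer(n_samples), gene_blocks = gene_blocks,
              n_sample_clusters = k,
              block_mean_matrix = as.matrix(block_mean_matrix),
              noise_sd = noise_sd, subtype_mixture = as.matrix(subtype_mixture),
              hazard_per_group = hazard_per_group, censor_max = censor_max,
              cnv_probs = as.matrix(cnv_probs), seed = as.integer(seed))
  if (length(cfg$gene_blocks) != 3L || is.null(names(cfg$gene_blocks)))
    emtStop("configError",
            "gene_blocks must be a named length-3 vector of block sizes")
  if (!all(dim(cfg$block_mean_matrix) == c(k, 3L)))
    emtStop("configError", "block_mean_matrix must be %d x 3", k)
  if (!all(dim(cfg$subtype_mixture) == c(k, length(.SUBTYPES))) ||
      any(abs(rowSums(cfg$subtype_mixture) - 1) > 1e-8))
    emtStop("configError",
            "subtype_mixture must be %d x %d with rows summing to 1", k,
            length(.SUBTYPES))
  if (length(cfg$hazard_per_group) != k || any(cfg$hazard_per_group <= 0))
    emtStop("configError", "hazard_per_group must be %d positive rates", k)
  if (!all(dim(cfg$cnv_probs) == c(k, 3L)) ||
      any(abs(rowSums(cfg$cnv_probs) - 1) > 1e-8))
    emtStop("configError", "cnv_probs must be %d x 3 with rows summing to 1",
            k)
  class(cfg) <- "CohortSimConfig"
  cfg
}

#' Simulate a block-structured expression cohort with clinical annotation
#'
#' Expression (log2 scale) is gene baseline + state-by-block mean shift +
#' Gaussian noise. Event times are exponential with the cluster's hazard and
#' censored at an independent uniform time on `[0, censor_max]`; subtype and
#' CNV category are multinomial per cluster.
#'
#' @param cfg a [cohortSimConfig()].
#' @param signature optional [SignatureSet-class] supplying gene names: the
#'   EMT-up block takes upregulated genes, the EMT-down block downregulated
#'   genes, and the partial-EMT block an alternating mixture (the published
#'   partial-EMT cluster mixes both directions). When omitted a matching
#'   synthetic signature is generated and returned in the truth.
#' @return A list with elements
#'   * `cohort`: [ExpressionMatrix-class] (`log2cpm` scale) with subtype,
#'     survival and CNV annotation in `colData`,
#'   * `annotation`: the same annotation as a plain `data.frame` with
#'     `sample_id`,
#'   * `truth`: `sample_cluster` (named integer), `gene_block` (named
#'     character) and `signature` ([SignatureSet-class]).
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_samples = 60, seed = 3))
#' table(sim$truth$sample_cluster)
#' @export
simulateCohort <- function(cfg, signature = NULL) {
  stopifnot(inherits(cfg, "CohortSimConfig"))
  nb <- cfg$gene_blocks
  nGenes <- sum(nb)
  upNeeded <- nb[["EMT-up"]] + ceiling(nb[["partial-EMT"]] / 2)
  downNeeded <- nb[["EMT-down"]] + floor(nb[["partial-EMT"]] / 2)
  if (is.null(signature)) {
    signature <- SignatureSet(up = sprintf("up%04d", seq_len(upNeeded)),
                              down = sprintf("dn%04d", seq_len(downNeeded)))
  } else {
    if (length(sigUp(signature)) < upNeeded ||
        length(sigDown(signature)) < downNeeded)
      emtStop("configError",
              "signature too small for gene_blocks: need %d up / %d down",
              upNeeded, downNeeded)
  }
  up <- sigUp(signature)[seq_len(upNeeded)]
  down <- sigDown(signature)[seq_len(downNeeded)]
  partial <- c(up[seq.int(nb[["EMT-up"]] + 1L,
                          length.out = ceiling(nb[["partial-EMT"]] / 2))],
               down[seq.int(nb[["EMT-down"]] + 1L,
                            length.out = floor(nb[["partial-EMT"]] / 2))])
  genes <- c(up[seq_len(nb[["EMT-up"]])], partial,
             down[seq_len(nb[["EMT-down"]])])
  block <- rep(c("EMT-up", "partial-EMT", "EMT-down"), times = nb)
  names(block) <- genes

  n <- cfg$n_samples
  samples <- sprintf("s%04d", seq_len(n))
  clu <- withStream(cfg$seed, "clusters",
                    sample.int(cfg$n_sample_clusters, n, replace = TRUE))
  names(clu) <- samples
  baseline <- withStream(cfg$seed, "gene-baseline",
                         stats::runif(nGenes, 3, 8))
  blockIdx <- match(block, colnames(cfg$block_mean_matrix))
  meanMat <- cfg$block_mean_matrix[clu, blockIdx, drop = FALSE]  # n x nGenes
  vals <- t(meanMat) + baseline +
    withStream(cfg$seed, "noise",
               matrix(stats::rnorm(nGenes * n, 0, cfg$noise_sd), nGenes, n))
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(genes, samples)

  subtype <- withStream(cfg$seed, "subtype", vapply(clu, function(g)
    sample(.SUBTYPES, 1L, prob = cfg$subtype_mixture[g, ]), character(1)))
  surv <- withStream(cfg$seed, "survival", {
    tEvent <- stats::rexp(n, rate = cfg$hazard_per_group[clu])
    tCens <- stats::runif(n, 0, cfg$censor_max)
    list(time = pmin(tEvent, tCens), event = as.integer(tEvent <= tCens))
  })
  cnv <- withStream(cfg$seed, "cnv", vapply(clu, function(g)
    sample(.CNV_LEVELS, 1L, prob = cfg$cnv_probs[g, ]), character(1)))

  annotation <- data.frame(sample_id = samples, cohort = "synthetic",
                           subtype = unname(subtype),
                           time_days = unname(surv$time),
                           event = unname(surv$event), cnv = unname(cnv),
                           stringsAsFactors = FALSE)
  cohort <- ExpressionMatrix(vals, "log2cpm",
                             sampleData = annotation[, -1L, drop = FALSE])
  list(cohort = cohort, annotation = annotation,
       truth = list(sample_cluster = clu, gene_block = block,
                    signature = signature))
}

#' Simulate a reference signature collection with controlled overlap
#'
#' Builds `n_sets` gene sets, each drawing `round(overlap_frac * size)` genes
#' from the query signature core and the remainder from the universe outside
#' the core, so the realised overlap fraction with the core is exact by
#' construction (up to the rounding rule).
#'
#' @param core a [SignatureSet-class] whose genes seed the overlap.
#' @param n_sets number of reference sets to generate.
#' @param overlap_fracs overlap fractions in `[0, 1]`, recycled over sets.
#' @param universe character vector of candidate gene identifiers (must cover
#'   the non-core remainder).
#' @param set_sizes set sizes, recycled over sets.
#' @param seed integer seed.
#' @return A [GeneSetCollection-class] with one entry per generated set.
#' @examples
#' core <- SignatureSet(up = sprintf("u%02d", 1:30),
#'                      down = sprintf("d%02d", 1:30))
#' db <- simulateSignatureDB(core, 5, 0.14, sprintf("x%03d", 1:500),
#'                           set_sizes = 100, seed = 2)
#' lengths(geneSets(db))
#' @export
simulateSignatureDB <- function(core, n_sets, overlap_fracs, universe,
                                set_sizes = 100L, seed = 1L) {
  stopifnot(is(core, "SignatureSet"))
  if (any(overlap_fracs < 0 | overlap_fracs > 1))
    emtStop("configError", "overlap fractions must lie in [0, 1]")
  coreGenes <- sigGenes(core)
  nonCore <- setdiff(universe, coreGenes)
  fracs <- rep_len(overlap_fracs, n_sets)
  sizes <- rep_len(as.integer(set_sizes), n_sets)
  withStream(seed, "signature-db", {
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      nCore <- round(fracs[i] * sizes[i])
      nOther <- sizes[i] - nCore
      if (nCore > length(coreGenes))
        emtStop("configError", "core too small for requested overlap (set %d)",
                i)
      if (nOther > length(nonCore))
        emtStop("configError",
                "universe too small: need %d non-core genes for set %d",
                nOther, i)
      sets[[i]] <- c(coreGenes[sample.int(length(coreGenes), nCore)],
                     nonCore[sample.int(length(nonCore), nOther)])
    }
    names(sets) <- sprintf("REF_%03d", seq_len(n_sets))
    GeneSetCollection(sets, stats::setNames(
      sprintf("synthetic reference signature, overlap %.2f", fracs),
      names(sets)))
  })
}
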