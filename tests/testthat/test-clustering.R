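randomExpr <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  ExpressionMatrix(matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
    dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                    sprintf("s%02d", seq_len(nSamples)))), "log2cpm")
}

test_that("correlation distance hits its analytic anchors", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  colnames(v) <- sprintf("s%d", 1:4)
  d <- correlationDistance(ExpressionMatrix(v, "log2cpm"), "gene")
  expect_equal(d["a", "b"], 0)            # identical profile shape
  expect_equal(d["a", "c"], 2)            # exact anti-correlation
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  vc <- rbind(v, d = c(5, 5, 5, 5))
  expect_error(correlationDistance(ExpressionMatrix(vc, "log2cpm"), "gene"),
               "d", class = "constantItemError")
})

test_that("correlation distance matches the naive pairwise formula", {
  for (seed in 1:20) {
    x <- randomExpr(10, 8, seed)
    d <- correlationDistance(x, "gene")
    v <- exprValues(x)
    for (i in 1:9) for (j in (i + 1):10) {
      r <- sum((v[i, ] - mean(v[i, ])) * (v[j, ] - mean(v[j, ]))) /
        (sqrt(sum((v[i, ] - mean(v[i, ]))^2)) *
           sqrt(sum((v[j, ] - mean(v[j, ]))^2)))
      expect_equal(d[i, j], 1 - r, tolerance = 1e-12)
    }
  }
})

test_that("hierarchical clustering separates blobs and respects boundaries", {
  pts <- c(0, 0.5, 1, 10, 10.5, 11)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("p%d", 1:6), sprintf("p%d", 1:6))
  out <- hcluster(d, distance = "euclidean")
  lab <- labelsAtK(out, 2)
  expect_length(unique(lab[1:3]), 1)
  expect_length(unique(lab[4:6]), 1)
  expect_false(lab[1] == lab[4])
  expect_length(unique(labelsAtK(out, 6)), 6)
  expect_error(labelsAtK(out, 7))
  # complete linkage merge heights are non-decreasing
  expect_true(all(diff(out@tree$height) >= -1e-12))
})

test_that("cutting at k then k+1 refines the partition", {
  x <- randomExpr(4, 30, 99)
  d <- correlationDistance(x, "sample")
  out <- hcluster(d)
  for (k in 2:8) {
    a <- labelsAtK(out, k)
    b <- labelsAtK(out, k + 1)
    # every finer cluster sits inside exactly one coarser cluster
    expect_true(all(vapply(split(a, b), function(v) length(unique(v)),
                           integer(1)) == 1L))
  }
})

test_that("stability indices reproduce the worked 1-D example", {
  m <- ExpressionMatrix(matrix(c(0, 1, 10, 11), 1,
    dimnames = list("g", sprintf("s%d", 1:4))), "log2cpm")
  prof <- stabilityScan(m, "sample", k_range = 2, L = 1,
                        distance = "euclidean")
  expect_equal(prof$connectivity, 0)
  expect_equal(prof$dunn, 9)
  expect_equal(prof$silhouette, (19 / 21 + 17 / 19) / 2, tolerance = 1e-10)
  expect_equal(prof$silhouette, 0.8997, tolerance = 1e-4)
})

test_that("stability indices match naive references on random data", {
  for (seed in 1:30) {
    set.seed(seed + 300)
    n <- sample(12:20, 1)
    pts <- matrix(rnorm(2 * n), n, 2,
                  dimnames = list(sprintf("i%02d", 1:n), c("x", "y")))
    d <- as.matrix(dist(pts))
    x <- ExpressionMatrix(t(pts), "log2cpm")
    L <- sample(2:4, 1)
    prof <- stabilityScan(x, "sample", k_range = 2:4, L = L,
                          distance = "euclidean")
    out <- attr(prof, "outcome")
    for (r in seq_len(nrow(prof))) {
      lab <- labelsAtK(out, prof$k[r])
      expect_equal(prof$connectivity[r], bruteConnectivity(d, lab, L),
                   tolerance = 1e-10)
      expect_equal(prof$dunn[r], bruteDunn(d, lab), tolerance = 1e-10)
      expect_equal(prof$silhouette[r], bruteSilhouette(d, lab),
                   tolerance = 1e-10)
    }
  }
})

test_that("silhouette tends to 1 and connectivity to 0 with separation", {
  sep <- function(gap) {
    v <- matrix(c(rnorm(10, 0, 0.1), rnorm(10, gap, 0.1)), 1)
    dimnames(v) <- list("g", sprintf("s%02d", 1:20))
    set.seed(1)
    stabilityScan(ExpressionMatrix(v, "log2cpm"), "sample", k_range = 2,
                  L = 3, distance = "euclidean")
  }
  set.seed(5)
  wide <- sep(100); narrow <- sep(1)
  expect_gt(wide$silhouette, narrow$silhouette)
  expect_gt(wide$silhouette, 0.95)
  expect_equal(wide$connectivity, 0)
})

test_that("selectK recommends by mean rank with ties to the smaller k", {
  prof <- data.frame(k = 2:4,
                     connectivity = c(5, 1, 9),
                     dunn = c(0.5, 2, 0.1),
                     silhouette = c(0.4, 0.9, 0.1))
  sel <- selectK(prof)
  expect_identical(sel$k, 3L)   # wins all three metrics
  expect_false(sel$tie)
  # connectivity prefers k=2, dunn prefers k=3, silhouette indifferent
  tie <- data.frame(k = 2:3, connectivity = c(1, 2), dunn = c(1, 2),
                    silhouette = c(0.5, 0.5))
  selTie <- selectK(tie)
  expect_identical(selTie$k, 2L)
  expect_true(selTie$tie)
})

test_that("selectK recovers the planted cluster count on synthetic cohorts", {
  hits <- 0
  for (seed in 1:5) {
    sim <- simulateCohort(cohortSimConfig(n_samples = 240, seed = seed))
    z <- rowZscore(sim$cohort, quiet = TRUE)
    prof <- stabilityScan(z, "sample", k_range = 2:8, L = 10)
    hits <- hits + (selectK(prof)$k == 6L)
  }
  expect_gte(hits, 4)
})

test_that("gene-cluster annotation follows the composition thresholds", {
  sig <- SignatureSet(up = sprintf("u%03d", 1:120),
                      down = sprintf("d%03d", 1:120))
  lab <- c(setNames(rep(1, 100), c(sprintf("u%03d", 1:91),
                                   sprintf("d%03d", 1:9))),
           setNames(rep(2, 10), c(sprintf("u%03d", 92:96),
                                  sprintf("d%03d", 10:14))),
           setNames(rep(3, 10), sprintf("d%03d", 15:24)))
  ann <- annotateGeneClusters(lab, sig)
  expect_equal(ann$frac_up, c(0.91, 0.5, 0))
  expect_identical(ann$label, c("EMT-up", "partial-EMT", "EMT-down"))
  # invariant under cluster relabeling
  relab <- setNames(c(3, 1, 2)[lab], names(lab))
  ann2 <- annotateGeneClusters(relab, sig)
  expect_setequal(paste(ann2$frac_up, ann2$label),
                  paste(ann$frac_up, ann$label))
  expect_error(annotateGeneClusters(c(lab, zzz = 4), sig), "zzz",
               class = "valueError")
})

test_that("composition table reports consistent counts and percentages", {
  lab <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  sub <- c("X", "X", "Y", "Y", "Y", "Y", "Y", "Y", "X", "X")
  tab <- compositionTable(lab, sub)
  expect_equal(sum(tab$counts), 10)
  expect_equal(unname(rowSums(tab$row_pct)), c(100, 100))
  expect_equal(unname(colSums(tab$col_pct)), c(100, 100))
  expect_equal(tab$col_pct["1", "X"], 50)   # half of X in cluster 1
  one <- compositionTable(rep(1, 4), rep("X", 4))
  expect_equal(unname(one$col_pct[1, 1]), 100)
  expect_error(compositionTable(c(1, NA), c("a", "b")), class = "valueError")
})
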