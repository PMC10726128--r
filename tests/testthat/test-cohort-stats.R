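test_that("Kaplan-Meier estimate matches the product-limit by hand", {
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(3 / 4, 1 / 2, 1 / 4, 0))
  expect_equal(km$n_risk, c(4, 3, 2, 1))
  allCens <- kmEstimate(c(5, 8, 11), c(0, 0, 0))
  expect_true(all(allCens$survival == 1))
  expect_error(kmEstimate(numeric(0), numeric(0)), class = "valueError")
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), class = "valueError")
})

test_that("KM equals the empirical survivor function without censoring", {
  for (seed in 1:25) {
    set.seed(seed)
    tm <- round(rexp(40, 0.01), 1)  # rounding forces ties
    km <- kmEstimate(tm, rep(1, 40))
    for (r in seq_len(nrow(km)))
      expect_equal(km$survival[r], bruteSurvivor(tm, km$time[r]),
                   tolerance = 1e-12)
  }
})

test_that("horizon truncation censors administratively, not by exclusion", {
  tm <- c(100, 2000, 3000)
  km <- kmEstimate(tm, c(1, 1, 1), horizon_days = 1826)
  expect_equal(max(km$time), 1826)
  expect_equal(sum(km$n_event), 1)           # only the in-window event
  expect_equal(km$n_risk[1], 3)              # nobody dropped
})

test_that("log-rank statistic behaves at its anchors", {
  # identical event-time multisets: no evidence of difference
  same <- logrankTest(rep(c(1, 2, 3), 2), rep(1, 6),
                      rep(c("a", "b"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # no events anywhere: flagged p = 1
  none <- logrankTest(c(1, 2, 3, 4), rep(0, 4), c("a", "a", "b", "b"))
  expect_true(none$no_events)
  expect_equal(none$p, 1)
  expect_error(logrankTest(1:3, c(1, 1, 1), rep("a", 3)),
               class = "valueError")
})

test_that("log-rank is invariant under group relabeling", {
  set.seed(41)
  tm <- rexp(60, 0.01); ev <- rbinom(60, 1, 0.7)
  g <- rep(c("a", "b", "c"), 20)
  a <- logrankTest(tm, ev, g)
  b <- logrankTest(tm, ev, c(a = "z", b = "x", c = "y")[g])
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
})

test_that("driver correlation recovers engineered correlations and the KW anchor", {
  n <- 40
  driver <- seq_len(n) + 0.5
  rTarget <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  v <- rbind(DRV = driver,
             t(vapply(seq_along(rTarget), function(i)
               exactCorrelationGene(driver, rTarget[i], 1000 + i),
               numeric(n))))
  rownames(v) <- c("DRV", sprintf("gene%d", 1:6))
  colnames(v) <- sprintf("s%02d", seq_len(n))
  x <- ExpressionMatrix(v, "log2cpm")
  clusters <- setNames(rep(c("EMT-down", "EMT-up"), each = 3),
                       sprintf("gene%d", 1:6))
  res <- driverCorrelation(x, "DRV", clusters)
  expect_equal(sort(res$table$r), rTarget, tolerance = 1e-10)
  # two groups of 3 with fully separated ranks: H = 3.857, p = 0.0495
  expect_equal(res$kw_h, 12 / (6 * 7) * (3 * 1.5^2 + 3 * 1.5^2),
               tolerance = 1e-10)
  expect_equal(res$kw_p, 0.0495, tolerance = 1e-3)
})

test_that("driver correlation excludes the driver from its own group", {
  set.seed(9)
  v <- matrix(rnorm(50, 6), 5, 10,
              dimnames = list(c("ZEB1", sprintf("g%d", 1:4)),
                              sprintf("s%02d", 1:10)))
  x <- ExpressionMatrix(v, "log2cpm")
  clusters <- setNames(c("EMT-up", "EMT-up", "EMT-up", "EMT-down",
                         "EMT-down"),
                       c("ZEB1", sprintf("g%d", 1:4)))
  res <- driverCorrelation(x, "ZEB1", clusters)
  expect_true(res$driver_excluded)
  expect_false("ZEB1" %in% res$table$gene_id)
  const <- ExpressionMatrix(rbind(v, FLAT = 5), "log2cpm")
  expect_error(driverCorrelation(const, "FLAT", clusters),
               class = "constantItemError")
})

test_that("two-group expression test covers its anchors and stars", {
  same <- groupExpressionTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 1e-10)
  expect_identical(same$stars, "ns")
  sep <- groupExpressionTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)  # U = 0: complete separation
  # no labelling of 3-vs-3 values gives a smaller normal-approximation p
  ps <- apply(combn(6, 3), 2, function(idx) {
    pool <- c(1, 2, 3, 10, 11, 12)
    groupExpressionTest(pool[idx], pool[-idx])$p
  })
  expect_equal(sep$p, min(ps), tolerance = 1e-12)
  expect_identical(starCode(0.004), "**")
  expect_identical(starCode(2e-5), "****")
  expect_error(groupExpressionTest(1, c(1, 2)), class = "valueError")
  tt <- groupExpressionTest(c(1, 2, 3), c(10, 11, 12), method = "t")
  expect_lt(tt$p, 0.001)
})

test_that("CNV thresholding maps signs to categories with exact percentages", {
  s <- cnvSummary(c(-1, 0, 1, 2, 2))
  expect_equal(s$pct[s$category == "deletion"], 20)
  expect_equal(s$pct[s$category == "normal"], 20)
  expect_equal(s$pct[s$category == "amplification"], 60)
  allZero <- cnvSummary(rep(0, 7))
  expect_equal(allZero$pct[allZero$category == "normal"], 100)
  byGroup <- cnvSummary(c(-2, 0, 2, 2), c("a", "a", "b", "b"))
  expect_equal(as.numeric(tapply(byGroup$pct, byGroup$group, sum)),
               c(100, 100))
  expect_equal(as.integer(tapply(byGroup$n, byGroup$group, sum)), c(2L, 2L))
  expect_error(cnvSummary(c(0, 3)), class = "valueError")
})

test_that("signature response classifies affected and non-affected genes", {
  sig <- SignatureSet(up = sprintf("u%02d", 1:50),
                      down = sprintf("d%02d", 1:50))
  genes <- sigGenes(sig)
  base <- setNames(rep(5, 100), genes)
  induced <- base + c(rep(2, 50), rep(-2, 50))   # full EMT response
  flat <- base                                    # no response at all
  v <- cbind(baseline = base, wt = induced, ko = flat)
  x <- ExpressionMatrix(v, "log2cpm")
  res <- signatureResponse(sig, x, baseline = "baseline")
  fr <- res$fractions
  wtUp <- fr$affected_pct[fr$condition == "wt" & fr$direction == "up"]
  koUp <- fr$affected_pct[fr$condition == "ko" & fr$direction == "up"]
  expect_equal(wtUp, 0)
  expect_equal(koUp, 100)
  expect_equal(fr$affected_pct[fr$condition == "ko" & fr$direction == "down"],
               100)
  expect_error(signatureResponse(sig, x, baseline = "nope"),
               class = "valueError")
})

test_that("signature response drops absent genes with a count", {
  sig <- SignatureSet(up = c("a", "b", "ghost"), down = "c")
  v <- matrix(c(1, 1, 1, 3, 1, 1), 3,
              dimnames = list(c("a", "b", "c"), c("baseline", "cond")))
  suppressMessages(res <- signatureResponse(sig, ExpressionMatrix(v, "log2cpm"),
                                            "baseline"))
  expect_equal(res$n_dropped, 1)
  expect_equal(nrow(res$per_gene), 3)
})
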