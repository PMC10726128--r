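# Independent brute-force reference implementations used to validate the
# package's vectorised/optimised code paths. These deliberately favour
# clarity over speed and never share code with the implementation.

# Step-up FDR adjustment, literal transcription of the procedure.
bruteStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, sorted[i] * m / i)
    adj[i] <- val
    prev <- val
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Full running-sum enrichment score by explicit loop over every rank.
# Sign convention at a magnitude tie (within 1e-12): the positive excursion.
bruteES <- function(scores, isHit, weight = 1) {
  N <- length(scores)
  m <- sum(isHit)
  nr <- sum(abs(scores[isHit])^weight)
  phit <- 0; pmiss <- 0
  maxD <- -Inf; minD <- Inf
  for (i in seq_len(N)) {
    if (isHit[i]) {
      phit <- phit + if (nr == 0) 1 / m else abs(scores[i])^weight / nr
    } else {
      pmiss <- pmiss + 1 / (N - m)
    }
    d <- phit - pmiss
    maxD <- max(maxD, d)
    minD <- min(minD, d)
  }
  if (maxD >= -minD - 1e-12) maxD else minD
}

# Naive stability indices, double loops over the distance matrix.
bruteConnectivity <- function(d, labels, L) {
  n <- nrow(d)
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(d[i, others])][seq_len(L)]
    for (j in seq_len(L))
      if (labels[nn[j]] != labels[i]) total <- total + 1 / j
  }
  total
}

bruteDunn <- function(d, labels) {
  n <- nrow(d)
  minInter <- Inf; maxDiam <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) maxDiam <- max(maxDiam, d[i, j])
      else minInter <- min(minInter, d[i, j])
    }
  }
  if (maxDiam == 0) Inf else minInter / maxDiam
}

bruteSilhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Empirical survivor fraction (no censoring): share of subjects alive after t.
bruteSurvivor <- function(times, t) mean(times > t)

# Convenience: a small labelled count ExpressionMatrix.
makeCounts <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  ExpressionMatrix(values, "counts")
}

# Vectors with an exact prescribed sample correlation to a driver: build an
# orthonormal basis (z1 = standardised driver, z2 orthogonal) and mix.
exactCorrelationGene <- function(driver, r, noiseSeed) {
  n <- length(driver)
  z1 <- (driver - mean(driver)) / sqrt(sum((driver - mean(driver))^2))
  set.seed(noiseSeed)
  raw <- rnorm(n)
  raw <- raw - mean(raw)
  raw <- raw - sum(raw * z1) * z1
  z2 <- raw / sqrt(sum(raw^2))
  r * z1 + sqrt(1 - r^2) * z2
}
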