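#' @include AllClasses.R
NULL

#' Read / write a gene-by-sample expression matrix (TSV)
#'
#' The interchange format is a UTF-8 tab-separated table whose header row is
#' `gene_id` followed by the sample identifiers, and whose first column holds
#' the gene identifiers. All cells must be numeric; duplicate gene or sample
#' identifiers are rejected with the offending identifier named.
#'
#' @param path path to a TSV file.
#' @param scale scale tag to attach to the values (see
#'   [ExpressionMatrix-class]); reading does not transform the numbers.
#' @return `readExpressionMatrix`: an [ExpressionMatrix-class].
#'   `writeExpressionMatrix`: the path, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- ExpressionMatrix(matrix(c(1, 3, 2, 4), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "counts")
#' writeExpressionMatrix(m, tf)
#' readExpressionMatrix(tf, "counts")
#' @export
readExpressionMatrix <- function(path, scale = c("counts", "cpm", "log2cpm",
                                                 "zscore")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) emtStop("parseError", "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L || colnames(df)[1L] != "gene_id")
    emtStop("parseError",
            "malformed header in %s: first column must be 'gene_id'", path)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    emtStop("parseError", "duplicate gene id(s): %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    emtStop("parseError", "duplicate sample id(s): %s",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      emtStop("parseError",
              "non-numeric value '%s' at gene '%s', sample '%s'",
              df[[j + 1L]][bad], genes[bad], samples[j])
    }
    vals[, j] <- v
  }
  ExpressionMatrix(vals, scale)
}

#' @param x an [ExpressionMatrix-class] to write.
#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = geneIds(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...` with at
#' least one member gene; lines with fewer than three fields are rejected with
#' the line number. Round-tripping preserves set names, order, descriptions
#' and membership.
#'
#' @param path path to a `.gmt` file.
#' @return `readGMT`: a [GeneSetCollection-class]. `writeGMT`: the path,
#'   invisibly.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeGMT(GeneSetCollection(list(S1 = c("A", "B"))), tf)
#' readGMT(tf)
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) emtStop("parseError", "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      emtStop("parseError",
              "GMT line %d has %d field(s); need name, description, >=1 gene",
              i, length(f))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      emtStop("parseError", "GMT line %d has no member genes", i)
    sets[[f[1L]]] <- genes
    descr[f[1L]] <- f[2L]
  }
  GeneSetCollection(sets, descr)
}

#' @param collection a [GeneSetCollection-class] to write.
#' @rdname readGMT
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  descr <- setDescriptions(collection)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descr[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

.ANNOT_COLS <- c("sample_id", "condition", "cohort", "subtype", "time_days",
                 "event", "cnv")

#' Read / write a per-sample annotation table (TSV)
#'
#' Fixed column names: `sample_id` (required, unique), and optionally
#' `condition` (`epithelial`/`mesenchymal`), `cohort`, `subtype`, `time_days`
#' (survival time in days, >= 0), `event` (0 censored / 1 event) and `cnv`
#' (`deletion`/`normal`/`amplification`). `time_days` and `event` must be
#' present (non-missing) for exactly the same samples.
#'
#' @param path path to a TSV file.
#' @return `readSampleAnnotation`: a `data.frame` with `sample_id` first.
#'   `writeSampleAnnotation`: the path, invisibly.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) emtStop("parseError", "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validateSampleAnnotation(df)
  df
}

#' @param annotation a `data.frame` as described above.
#' @rdname readSampleAnnotation
#' @export
writeSampleAnnotation <- function(annotation, path) {
  validateSampleAnnotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname readSampleAnnotation
#' @description `validateSampleAnnotation` checks the invariants and returns
#'   the table invisibly; it is called by both reader and writer.
#' @export
validateSampleAnnotation <- function(annotation) {
  if (!"sample_id" %in% colnames(annotation))
    emtStop("parseError", "annotation must contain a 'sample_id' column")
  unknown <- setdiff(colnames(annotation), .ANNOT_COLS)
  if (length(unknown))
    emtStop("parseError", "unknown annotation column(s): %s",
            paste(unknown, collapse = ", "))
  ids <- annotation$sample_id
  if (anyDuplicated(ids))
    emtStop("parseError", "duplicate sample_id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if ("condition" %in% colnames(annotation)) {
    bad <- setdiff(stats::na.omit(annotation$condition),
                   c("epithelial", "mesenchymal"))
    if (length(bad))
      emtStop("parseError", "invalid condition value(s): %s",
              paste(bad, collapse = ", "))
  }
  hasT <- "time_days" %in% colnames(annotation)
  hasE <- "event" %in% colnames(annotation)
  if (hasT != hasE)
    emtStop("parseError", "'time_days' and 'event' must be given together")
  if (hasT) {
    t <- annotation$time_days; e <- annotation$event
    if (any(is.na(t) != is.na(e)))
      emtStop("parseError",
              "'event' must be present for exactly the samples with 'time_days'")
    if (any(t < 0, na.rm = TRUE))
      emtStop("parseError", "'time_days' must be >= 0")
    if (!all(stats::na.omit(e) %in% c(0, 1)))
      emtStop("parseError", "'event' must be 0 or 1")
  }
  if ("cnv" %in% colnames(annotation)) {
    bad <- setdiff(stats::na.omit(annotation$cnv),
                   c("deletion", "normal", "amplification"))
    if (length(bad))
      emtStop("parseError", "invalid cnv value(s): %s",
              paste(bad, collapse = ", "))
  }
  invisible(annotation)
}
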