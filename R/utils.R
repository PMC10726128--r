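## Internal helpers shared across modules.

emtStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "emtsigError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

## Deterministic per-component RNG stream: a single user seed fans out to one
## sub-seed per named component, so adding a new generator never perturbs the
## draws of existing ones. Sub-seeds stay within the 32-bit integer range.
streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

withStream <- function(seed, stream, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(streamSeed(seed, stream))
  expr
}

## Drop signature genes absent from a matrix, reporting the count (mirrors the
## published workflow where 263/265 and 246/265 signature genes were found in
## the external cohorts).
dropAbsentGenes <- function(sig, geneUniverse, quiet = FALSE) {
  up <- intersect(sigUp(sig), geneUniverse)
  down <- intersect(sigDown(sig), geneUniverse)
  dropped <- setdiff(sigGenes(sig), c(up, down))
  if (length(dropped) && !quiet)
    message(length(dropped), " of ", length(sigGenes(sig)),
            " signature genes not found in the matrix; dropped")
  list(signature = SignatureSet(up = up, down = down,
                                provenance = sigProvenance(sig)),
       dropped = dropped)
}
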