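#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils read.delim write.table head
NULL

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Filter/accounting messages. All ingest-time drops go through here so every
# run leaves a reproducible trail of counts.
log_filter <- function(what, n) {
  if (n > 0) message(sprintf("[degnet] %s: %d", what, n))
  invisible(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Closed set of gene biotype categories used throughout.
LOCUS_GROUPS <- c("protein_coding", "ncRNA", "pseudogene", "other")
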