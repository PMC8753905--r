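# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators do not disturb the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic derived seeds: one master seed fans out to per-stage /
# per-replicate streams. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index)) %% 2147483647
}

# Half-open bp intervals (0-based) -> GRanges (1-based closed, as IRanges).
intervals_to_granges <- function(chrom, start_bp, end_bp) {
  stopifnot(all(end_bp >= start_bp))
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start_bp + 1, end = end_bp)
  )
}

# GRanges -> data.frame of half-open 0-based intervals.
granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Point positions (0-based bp) -> width-1 GRanges.
points_to_granges <- function(chrom, pos0) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = pos0 + 1, width = 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
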