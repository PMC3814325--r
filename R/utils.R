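## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's
#' RNG state afterwards.
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required for every randomized operation")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Centered moving average with shrinking (partial) windows at the edges,
#' so the result has the same length as the input.
#' @noRd
movingAverage <- function(x, width) {
  if (width %% 2L != 1L) stop("smoothing width must be odd")
  if (width == 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @noRd
isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @noRd
altEventCategories <- function() {
  c("cassette_exon", "retained_intron", "alt_5ss", "alt_3ss",
    "alt_promoter", "alt_terminator")
}

#' @noRd
mapAnchors <- function() {
  c("upstream_exon_5ss", "cassette_3ss", "cassette_5ss", "downstream_exon_3ss")
}

## concatenate GRanges quietly (per-feature objects carry disjoint
## seqlevels; the seqinfo-merge warning is pure metadata noise here)
#' @noRd
combineGRanges <- function(lst) {
  lst <- lst[lengths(lst) > 0L | vapply(lst, is, logical(1), "GRanges")]
  suppressWarnings(do.call(c, lst))
}

## random integers in [lo, hi], vectorized over n
#' @noRd
runifInt <- function(n, lo, hi) {
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}
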