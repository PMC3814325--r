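## Splicing quantification formulas (gel band ratios, knockdown
## reductions, ddCt) and the AS-NMD predictor for exon-skip isoforms.

#' Exon skipping ratio from band intensities
#'
#' `ratio = skipped / (skipped + included)`; the complementary inclusion
#' ratio is `1 - ratio` exactly.
#'
#' @param skipped,included band intensities (non-negative, vectorized;
#'   not both zero in any pair).
#' @return data.frame with `skipping_ratio` and `inclusion_ratio`.
#' @export
skippingRatio <- function(skipped, included) {
  stopifnot(length(skipped) == length(included))
  if (any(skipped < 0 | included < 0))
    stop("band intensities must be non-negative")
  if (any(skipped + included == 0))
    stop("both band intensities are zero")
  r <- skipped / (skipped + included)
  data.frame(skipping_ratio = r, inclusion_ratio = 1 - r)
}

#' Isoform level relative to mock transfection
#'
#' @param treated isoform level after treatment (>= 0).
#' @param mock level in the mock transfection (> 0).
#' @return `treated / mock` (vectorized).
#' @export
reductionRelativeToMock <- function(treated, mock) {
  if (any(mock <= 0)) stop("mock level must be > 0")
  if (any(treated < 0)) stop("treated level must be >= 0")
  treated / mock
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`, the standard qRT-PCR
#' quantification against a reference gene.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetCtrl,ctRefCtrl finite Ct
#'   values (vectorized).
#' @return relative expression.
#' @export
ddctRelativeExpression <- function(ctTargetTreated, ctRefTreated,
                                   ctTargetCtrl, ctRefCtrl) {
  vals <- c(ctTargetTreated, ctRefTreated, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ctTargetTreated - ctRefTreated) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}

#' Remove an internal exon from a transcript
#'
#' Produces the exon-skip isoform: the exon (transcript-order index) is
#' removed, downstream transcript coordinates shift by its length, and
#' the CDS start is preserved (the start codon must lie upstream of the
#' removed exon). The removed width is recorded in the result's metadata
#' for frame bookkeeping by [predictNmd()].
#'
#' @param tx a coding [TranscriptModel-class] with at least 3 exons.
#' @param exonIndex transcript-order index of the exon to remove; must
#'   be internal (not first or last).
#' @return a new [TranscriptModel-class] (non-reference isoform).
#' @export
skipExon <- function(tx, exonIndex) {
  exTx <- exonsInTranscriptOrder(tx)
  ne <- length(exTx)
  if (ne < 3L) stop("transcript must have at least 3 exons")
  if (exonIndex <= 1L || exonIndex >= ne)
    stop("cannot skip a first or last exon")
  w <- GenomicRanges::width(exTx)
  cb <- cumsum(c(0L, w))
  a <- cb[exonIndex] + 1L; b <- cb[exonIndex + 1L]   # transcript span
  wRm <- w[exonIndex]
  cs <- tx@cdsStart; ce <- tx@cdsEnd
  if (!isCoding(tx)) stop("transcript is non-coding")
  if (cs + 2L >= a && cs <= b)
    stop("start codon lies inside the removed exon")
  if (cs >= a) stop("start codon must be upstream of the removed exon")
  newCe <- if (ce > b) ce - wRm else if (ce >= a) a - 1L else ce
  keep <- exTx[-exonIndex]
  out <- TranscriptModel(paste0(tx@transcriptId, "_skip", exonIndex),
                         tx@geneId, BiocGenerics::sort(keep),
                         cdsStart = cs, cdsEnd = as.integer(newCe),
                         exonRole = tx@exonRole[
                           match(paste(GenomicRanges::start(BiocGenerics::sort(keep))),
                                 paste(GenomicRanges::start(tx@exons)))],
                         reference = FALSE)
  out@meta$removedExonWidth <- wRm
  out@meta$parent <- tx@transcriptId
  out
}

#' Predict nonsense-mediated decay of a transcript isoform
#'
#' Translates from the CDS start in frame until the first stop codon
#' (UAA/UAG/UGA). A premature termination codon (PTC) exists when the
#' first stop precedes the annotated stop; the transcript is predicted
#' to be an NMD substrate when the PTC lies more than `junctionRule` nt
#' (default 50, the canonical exon-junction rule) upstream of the last
#' exon-exon junction. PTC positions are the first base of the stop
#' codon, in 1-based transcript coordinates.
#'
#' @param tx a coding [TranscriptModel-class].
#' @param txSeq the spliced transcript sequence (character, `DNAString`
#'   or `RNAString`); its length must match the model.
#' @param junctionRule distance threshold in nt.
#' @return list of class `NmdCall` with fields `frameshift` (`NA` when
#'   the isoform was not produced by [skipExon()]), `ptcPosition`,
#'   `lastJunctionPosition`, `ptcToLastJunction`, `noStop`, `nmd`.
#' @export
predictNmd <- function(tx, txSeq, junctionRule = 50L) {
  if (!isCoding(tx)) stop("transcript is non-coding; NMD prediction needs a CDS")
  seq <- toupper(chartr("Uu", "Tt", as.character(txSeq)))
  L <- transcriptLength(tx)
  if (nchar(seq) != L)
    stop("sequence length ", nchar(seq), " does not match transcript length ", L)
  cs <- tx@cdsStart; ce <- tx@cdsEnd
  stops <- c("TAA", "TAG", "TGA")
  starts <- seq.int(cs, L - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% stops)
  firstStop <- if (length(hit)) starts[hit[1L]] else NA_integer_
  exTx <- exonsInTranscriptOrder(tx)
  lastJunction <- L - GenomicRanges::width(exTx)[length(exTx)]
  annotStopStart <- ce - 2L
  noStop <- is.na(firstStop)
  ptc <- !noStop && firstStop < annotStopStart
  ptcPos <- if (ptc) firstStop else NA_integer_
  dist <- if (ptc) lastJunction - ptcPos else NA_integer_
  rmw <- tx@meta$removedExonWidth
  frameshift <- if (is.null(rmw)) NA else (rmw %% 3L != 0L)
  structure(list(frameshift = frameshift,
                 ptcPosition = ptcPos,
                 lastJunctionPosition = as.integer(lastJunction),
                 ptcToLastJunction = if (ptc) as.integer(dist) else NA_integer_,
                 noStop = noStop,
                 nmd = isTRUE(ptc) && isTRUE(dist > junctionRule)),
            class = "NmdCall")
}

#' @export
print.NmdCall <- function(x, ...) {
  cat("NmdCall:",
      if (isTRUE(x$nmd)) "predicted NMD substrate" else "not an NMD substrate",
      "\n  frameshift:", x$frameshift,
      "\n  PTC position:", x$ptcPosition,
      "\n  last junction:", x$lastJunctionPosition,
      "\n  PTC-to-junction:", x$ptcToLastJunction, "nt\n")
  invisible(x)
}
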