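#' @import methods
#' @importFrom GenomicRanges GRanges strand seqnames start end width
#'   findOverlaps countOverlaps reduce coverage
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#'   metadata metadata<-
#' @importFrom BiocGenerics sort
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo seqinfo<- Seqinfo
NULL

setClassUnion("integerOrNA", "integer")

#' TranscriptModel: a single transcript isoform
#'
#' Holds the exon structure of one transcript together with its coding
#' region expressed in transcript coordinates (1-based, counted from the
#' transcript 5' end over the spliced sequence) and a per-exon role flag
#' (`constitutive`, `cassette` or `other`). Exons are stored in genomic
#' order; transcript order is strand dependent.
#'
#' @slot transcriptId single character identifier.
#' @slot geneId identifier of the host gene.
#' @slot exons `GRanges` of exons, all on one chromosome and strand,
#'   pairwise non-overlapping.
#' @slot cdsStart,cdsEnd 1-based transcript coordinates of the first base
#'   of the start codon and the last base of the stop codon; `NA` for a
#'   non-coding transcript.
#' @slot exonRole character vector parallel to `exons`.
#' @slot meta free-form list (used e.g. to record the width of an exon
#'   removed by [skipExon()]).
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    exons = "GRanges",
    cdsStart = "integer",
    cdsEnd = "integer",
    exonRole = "character",
    meta = "list"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "transcript has no exons")
  if (length(unique(as.character(GenomicRanges::seqnames(ex)))) > 1L)
    msg <- c(msg, "exons span multiple chromosomes")
  str <- unique(as.character(GenomicRanges::strand(ex)))
  if (length(str) > 1L || !str %in% c("+", "-"))
    msg <- c(msg, "exons must share a single strand ('+' or '-')")
  if (length(ex) > 1L) {
    o <- order(GenomicRanges::start(ex))
    s <- GenomicRanges::start(ex)[o]; e <- GenomicRanges::end(ex)[o]
    if (any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exons overlap")
  }
  if (length(object@exonRole) != length(ex))
    msg <- c(msg, "exonRole must be parallel to exons")
  if (!all(object@exonRole %in% c("constitutive", "cassette", "other")))
    msg <- c(msg, "exonRole values must be constitutive/cassette/other")
  L <- sum(GenomicRanges::width(ex))
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (!is.na(cs) || !is.na(ce)) {
    if (is.na(cs) || is.na(ce)) msg <- c(msg, "cdsStart/cdsEnd must both be set or both NA")
    else if (cs < 1L || ce > L || cs >= ce)
      msg <- c(msg, "CDS must satisfy 1 <= cdsStart < cdsEnd <= transcript length")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId identifiers.
#' @param exons `GRanges` of exons (one chromosome, one strand).
#' @param cdsStart,cdsEnd CDS bounds in 1-based transcript coordinates, or
#'   `NA` for a non-coding transcript. For a reference (all-exon) isoform
#'   the CDS length must be divisible by 3; pass `reference = FALSE` to
#'   lift that check (frameshifted exon-skip isoforms).
#' @param exonRole per-exon role flags; defaults to `"other"`.
#' @param reference logical; enforce the in-frame CDS-length invariant.
#' @return a [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(transcriptId, geneId, exons,
                            cdsStart = NA_integer_, cdsEnd = NA_integer_,
                            exonRole = rep("other", length(exons)),
                            reference = TRUE) {
  exons <- BiocGenerics::sort(exons)
  cdsStart <- as.integer(cdsStart); cdsEnd <- as.integer(cdsEnd)
  if (reference && !is.na(cdsStart) && !is.na(cdsEnd) &&
      (cdsEnd - cdsStart + 1L) %% 3L != 0L)
    stop("CDS length of a reference isoform must be divisible by 3 (",
         transcriptId, ")")
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      exons = exons, cdsStart = cdsStart, cdsEnd = cdsEnd,
      exonRole = as.character(exonRole), meta = list())
}

#' GeneModel: a gene with its transcript isoforms
#'
#' @slot geneId identifier.
#' @slot transcripts list of [TranscriptModel-class].
#' @slot expressed logical flag standing in for an expression filter
#'   (e.g. genes detected by RNA-seq in the assayed cell line).
#' @slot span `GRanges` of length 1 covering all transcript exons.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    transcripts = "list",
    expressed = "logical",
    span = "GRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@span) != 1L) msg <- c(msg, "span must have length 1")
  if (!length(object@transcripts)) msg <- c(msg, "gene has no transcripts")
  for (tx in object@transcripts) {
    if (!is(tx, "TranscriptModel")) { msg <- c(msg, "transcripts must be TranscriptModel"); break }
    ex <- tx@exons
    if (length(object@span) == 1L &&
        (any(GenomicRanges::start(ex) < GenomicRanges::start(object@span)) ||
         any(GenomicRanges::end(ex) > GenomicRanges::end(object@span))))
      msg <- c(msg, "span does not cover all transcript exons")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#' @param geneId identifier.
#' @param transcripts list of [TranscriptModel-class].
#' @param expressed logical expression flag.
#' @return a [GeneModel-class] object. The gene span is derived from the
#'   transcript exons.
#' @export
GeneModel <- function(geneId, transcripts, expressed = TRUE) {
  if (is(transcripts, "TranscriptModel")) transcripts <- list(transcripts)
  allex <- do.call(c, lapply(transcripts, function(tx) tx@exons))
  span <- range(allex)
  new("GeneModel", geneId = geneId, transcripts = transcripts,
      expressed = isTRUE(expressed), span = span)
}

## ---- accessors ----

#' @describeIn TranscriptModel transcript identifier
#' @param object a TranscriptModel or GeneModel
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))
setMethod("transcriptId", "TranscriptModel", function(object) object@transcriptId)

#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @describeIn TranscriptModel host gene identifier
setMethod("geneId", "TranscriptModel", function(object) object@geneId)
#' @describeIn GeneModel gene identifier
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @export
setGeneric("exons", function(object) standardGeneric("exons"))
#' @describeIn TranscriptModel exon `GRanges` in genomic order
setMethod("exons", "TranscriptModel", function(object) object@exons)

#' @export
setGeneric("exonRole", function(object) standardGeneric("exonRole"))
#' @describeIn TranscriptModel per-exon role flags
setMethod("exonRole", "TranscriptModel", function(object) object@exonRole)

#' @export
setGeneric("cdsStart", function(object) standardGeneric("cdsStart"))
#' @describeIn TranscriptModel CDS start (transcript coordinate)
setMethod("cdsStart", "TranscriptModel", function(object) object@cdsStart)

#' @export
setGeneric("cdsEnd", function(object) standardGeneric("cdsEnd"))
#' @describeIn TranscriptModel CDS end (transcript coordinate)
setMethod("cdsEnd", "TranscriptModel", function(object) object@cdsEnd)

#' @export
setGeneric("transcripts", function(object) standardGeneric("transcripts"))
#' @describeIn GeneModel list of transcript models
setMethod("transcripts", "GeneModel", function(object) object@transcripts)

#' @export
setGeneric("isExpressed", function(object) standardGeneric("isExpressed"))
#' @describeIn GeneModel expression flag
setMethod("isExpressed", "GeneModel", function(object) object@expressed)

#' @export
setGeneric("geneSpan", function(object) standardGeneric("geneSpan"))
#' @describeIn GeneModel genomic span covering all exons
setMethod("geneSpan", "GeneModel", function(object) object@span)

#' Transcript length (spliced)
#' @param tx a [TranscriptModel-class]
#' @return integer number of nucleotides in the mature transcript.
#' @export
transcriptLength <- function(tx) sum(GenomicRanges::width(tx@exons))

#' Is the transcript coding?
#' @param tx a [TranscriptModel-class]
#' @return logical
#' @export
isCoding <- function(tx) !is.na(tx@cdsStart) && !is.na(tx@cdsEnd)

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(gene %s): %d exons, %d nt%s\n",
              object@geneId, length(object@exons), transcriptLength(object),
              if (isCoding(object))
                sprintf(", CDS %d-%d", object@cdsStart, object@cdsEnd)
              else ", non-coding"))
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId,
      sprintf(": %d transcript(s), span %s:%d-%d(%s), expressed=%s\n",
              length(object@transcripts),
              as.character(GenomicRanges::seqnames(object@span)),
              GenomicRanges::start(object@span),
              GenomicRanges::end(object@span),
              as.character(GenomicRanges::strand(object@span)),
              object@expressed))
})

## ---- transcript coordinate arithmetic ----

#' Exons in transcript (5'->3') order
#' @param tx a [TranscriptModel-class]
#' @return `GRanges` ordered from the transcript 5' end.
#' @export
exonsInTranscriptOrder <- function(tx) {
  ex <- tx@exons
  if (as.character(GenomicRanges::strand(ex))[1L] == "-") rev(ex) else ex
}

#' Map a transcript interval to genomic ranges
#'
#' @param tx a [TranscriptModel-class]
#' @param tStart,tEnd 1-based transcript coordinates (inclusive).
#' @return `GRanges` of the genomic pieces (one per overlapped exon), in
#'   genomic order.
#' @export
transcriptToGenomic <- function(tx, tStart, tEnd) {
  L <- transcriptLength(tx)
  if (tStart < 1L || tEnd > L || tStart > tEnd)
    stop("transcript interval out of bounds")
  ex <- exonsInTranscriptOrder(tx)
  w <- GenomicRanges::width(ex)
  cb <- cumsum(c(0L, w))          # cumulative bases before each exon
  minus <- as.character(GenomicRanges::strand(ex))[1L] == "-"
  pieces <- list()
  for (i in seq_along(ex)) {
    lo <- max(tStart, cb[i] + 1L); hi <- min(tEnd, cb[i] + w[i])
    if (lo > hi) next
    off1 <- lo - cb[i]; off2 <- hi - cb[i]  # 1-based offsets within exon
    if (!minus) {
      gs <- GenomicRanges::start(ex)[i] + off1 - 1L
      ge <- GenomicRanges::start(ex)[i] + off2 - 1L
    } else {
      ge <- GenomicRanges::end(ex)[i] - off1 + 1L
      gs <- GenomicRanges::end(ex)[i] - off2 + 1L
    }
    pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ex)[i], IRanges::IRanges(gs, ge),
      strand = GenomicRanges::strand(ex)[i])
  }
  BiocGenerics::sort(do.call(c, pieces))
}

#' Map a genomic position to a transcript coordinate
#'
#' @param tx a [TranscriptModel-class]
#' @param gpos genomic position (1-based); must fall in an exon.
#' @return 1-based transcript coordinate.
#' @export
genomicToTranscript <- function(tx, gpos) {
  ex <- exonsInTranscriptOrder(tx)
  w <- GenomicRanges::width(ex)
  cb <- cumsum(c(0L, w))
  minus <- as.character(GenomicRanges::strand(ex))[1L] == "-"
  for (i in seq_along(ex)) {
    s <- GenomicRanges::start(ex)[i]; e <- GenomicRanges::end(ex)[i]
    if (gpos >= s && gpos <= e) {
      off <- if (!minus) gpos - s + 1L else e - gpos + 1L
      return(cb[i] + off)
    }
  }
  stop("position ", gpos, " is not exonic in transcript ", tx@transcriptId)
}

#' Spliced transcript sequence
#'
#' Extracts and splices the exon sequences from a genome, reverse
#' complementing for minus-strand transcripts.
#'
#' @param tx a [TranscriptModel-class]
#' @param genome a named `DNAStringSet` (one entry per chromosome).
#' @return a `DNAString` of length [transcriptLength()].
#' @export
transcriptSequence <- function(tx, genome) {
  ex <- tx@exons
  chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  contig <- genome[[chrom]]
  if (max(GenomicRanges::end(ex)) > length(contig))
    stop("exon beyond contig end on ", chrom)
  parts <- lapply(seq_along(ex), function(i)
    Biostrings::subseq(contig, GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i]))
  seq <- do.call(Biostrings::xscat, parts)
  if (as.character(GenomicRanges::strand(ex))[1L] == "-")
    seq <- Biostrings::reverseComplement(seq)
  seq
}
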