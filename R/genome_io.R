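## Readers/writers for BED6 tag libraries, GTF annotation and the
## alternative-splicing event table, plus genomic-region classification
## of CLIP clusters.

#' Read a BED6 file of CLIP tags
#'
#' Tags are returned as a `GRanges` (1-based closed coordinates; the BED
#' 0-based half-open convention is converted at this boundary). The
#' strand column is mandatory because every downstream operation is
#' strand-aware. Malformed lines are reported with their line numbers.
#'
#' @param path path to a 6-column BED file (chrom, start, end, name,
#'   score, strand; tab- or space-separated).
#' @param library which library the tags belong to (`"clip"` or
#'   `"control"`); stored in `mcols(x)$library`.
#' @return `GRanges` with metadata columns `tagId`, `score`, `library`.
#' @export
readTagsBed <- function(path, library = c("clip", "control")) {
  library <- match.arg(library)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      tagId = character(), score = numeric(), library = character())
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("BED line(s) ", paste(lineno[nf < 6L], collapse = ", "),
         ": expected 6 columns (chrom, start, end, name, score, strand); ",
         "the strand column is required")
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("BED line(s) ", paste(lineno[bad], collapse = ", "),
         ": non-integer start/end")
  bad <- start0 < 0L | start0 >= end0
  if (any(bad))
    stop("BED line(s) ", paste(lineno[bad], collapse = ", "),
         ": require 0 <= start < end")
  bad <- !m[, 6L] %in% c("+", "-")
  if (any(bad))
    stop("BED line(s) ", paste(lineno[bad], collapse = ", "),
         ": strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(
    m[, 1L], IRanges::IRanges(start0 + 1L, end0), strand = m[, 6L],
    tagId = m[, 4L],
    score = suppressWarnings(as.numeric(m[, 5L])),
    library = library)
  gr
}

#' Write tags or clusters as BED6
#'
#' The inverse of [readTagsBed()]: 1-based closed `GRanges` coordinates
#' are written 0-based half-open.
#'
#' @param x a `GRanges`; `mcols(x)$tagId` (or `name`) supplies the name
#'   column, `mcols(x)$score` the score (default 0).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTagsBed <- function(x, path) {
  mc <- S4Vectors::mcols(x)
  nm <- if (!is.null(mc$tagId)) mc$tagId
        else if (!is.null(mc$name)) mc$name
        else sprintf("feature_%d", seq_along(x))
  sc <- if (!is.null(mc$score)) mc$score else rep(0, length(x))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = nm, score = sc,
    strand = as.character(GenomicRanges::strand(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- alternative splicing events ----

#' Construct an alternative-splicing event set
#'
#' Events are held in a `GRanges` whose range is the event interval, with
#' the flanking introns and exons (named in transcript orientation:
#' "upstream" is toward the transcript 5' end) as metadata coordinates.
#' The validity check enforces that the five components tile a contiguous
#' genomic block.
#'
#' @param eventId character vector of identifiers.
#' @param category event categories; one of `cassette_exon`,
#'   `retained_intron`, `alt_5ss`, `alt_3ss`, `alt_promoter`,
#'   `alt_terminator`.
#' @param chrom,strand chromosome and strand of each event.
#' @param eventStart,eventEnd 1-based closed bounds of the event interval.
#' @param upExonStart,upExonEnd,upIntronStart,upIntronEnd bounds of the
#'   upstream flanking exon/intron (transcript orientation).
#' @param downIntronStart,downIntronEnd,downExonStart,downExonEnd bounds
#'   of the downstream flanking intron/exon.
#' @param hostGene gene identifiers.
#' @param flankingConstitutive logical: are both flanking exons
#'   constitutive?
#' @return `GRanges` with the event metadata columns.
#' @export
altEvents <- function(eventId, category, chrom, strand,
                      eventStart, eventEnd,
                      upExonStart, upExonEnd, upIntronStart, upIntronEnd,
                      downIntronStart, downIntronEnd,
                      downExonStart, downExonEnd,
                      hostGene, flankingConstitutive) {
  stopifnot(all(category %in% altEventCategories()))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.integer(eventStart), as.integer(eventEnd)),
    strand = strand,
    eventId = as.character(eventId), category = as.character(category),
    upExonStart = as.integer(upExonStart), upExonEnd = as.integer(upExonEnd),
    upIntronStart = as.integer(upIntronStart), upIntronEnd = as.integer(upIntronEnd),
    downIntronStart = as.integer(downIntronStart), downIntronEnd = as.integer(downIntronEnd),
    downExonStart = as.integer(downExonStart), downExonEnd = as.integer(downExonEnd),
    hostGene = as.character(hostGene),
    flankingConstitutive = as.logical(flankingConstitutive))
  validateAltEvents(gr)
  gr
}

#' Check the abutment invariant of an event set
#'
#' In transcript orientation the components run upstream exon, upstream
#' intron, event, downstream intron, downstream exon without gaps; on the
#' minus strand the genomic order is reversed.
#'
#' @param events `GRanges` as built by [altEvents()].
#' @return invisibly `TRUE`; errors naming the offending event otherwise.
#' @export
validateAltEvents <- function(events) {
  if (!length(events)) return(invisible(TRUE))
  mc <- S4Vectors::mcols(events)
  minus <- as.character(GenomicRanges::strand(events)) == "-"
  es <- GenomicRanges::start(events); ee <- GenomicRanges::end(events)
  for (i in seq_along(events)) {
    if (!minus[i]) {
      blocks <- rbind(
        c(mc$upExonStart[i], mc$upExonEnd[i]),
        c(mc$upIntronStart[i], mc$upIntronEnd[i]),
        c(es[i], ee[i]),
        c(mc$downIntronStart[i], mc$downIntronEnd[i]),
        c(mc$downExonStart[i], mc$downExonEnd[i]))
    } else {
      blocks <- rbind(
        c(mc$downExonStart[i], mc$downExonEnd[i]),
        c(mc$downIntronStart[i], mc$downIntronEnd[i]),
        c(es[i], ee[i]),
        c(mc$upIntronStart[i], mc$upIntronEnd[i]),
        c(mc$upExonStart[i], mc$upExonEnd[i]))
    }
    if (any(blocks[, 1L] > blocks[, 2L]) ||
        any(blocks[-1L, 1L] != blocks[-nrow(blocks), 2L] + 1L))
      stop("event components do not abut for event ", mc$eventId[i])
  }
  invisible(TRUE)
}

#' Read an alternative-splicing event table
#'
#' Expects a TSV with header columns `event_id, category, chrom, strand,
#' event_start, event_end, upstream_exon_start, upstream_exon_end,
#' upstream_intron_start, upstream_intron_end, downstream_intron_start,
#' downstream_intron_end, downstream_exon_start, downstream_exon_end,
#' host_gene, flanking_constitutive` (1-based closed coordinates). Rows
#' with a category outside the supported set are skipped; a single
#' warning reports how many.
#'
#' @param path path to the TSV.
#' @return `GRanges` event set as from [altEvents()], with the number of
#'   skipped rows in `metadata(x)$skipped`.
#' @export
readAltEvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  known <- df$category %in% altEventCategories()
  nskip <- sum(!known)
  if (nskip > 0L)
    warning("skipped ", nskip, " event row(s) with unknown category")
  df <- df[known, , drop = FALSE]
  ev <- altEvents(
    df$event_id, df$category, df$chrom, df$strand,
    df$event_start, df$event_end,
    df$upstream_exon_start, df$upstream_exon_end,
    df$upstream_intron_start, df$upstream_intron_end,
    df$downstream_intron_start, df$downstream_intron_end,
    df$downstream_exon_start, df$downstream_exon_end,
    df$host_gene, df$flanking_constitutive)
  S4Vectors::metadata(ev)$skipped <- nskip
  ev
}

#' Write an event set as TSV
#' @param events `GRanges` from [altEvents()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAltEvents <- function(events, path) {
  mc <- S4Vectors::mcols(events)
  df <- data.frame(
    event_id = mc$eventId, category = mc$category,
    chrom = as.character(GenomicRanges::seqnames(events)),
    strand = as.character(GenomicRanges::strand(events)),
    event_start = GenomicRanges::start(events),
    event_end = GenomicRanges::end(events),
    upstream_exon_start = mc$upExonStart, upstream_exon_end = mc$upExonEnd,
    upstream_intron_start = mc$upIntronStart, upstream_intron_end = mc$upIntronEnd,
    downstream_intron_start = mc$downIntronStart,
    downstream_intron_end = mc$downIntronEnd,
    downstream_exon_start = mc$downExonStart,
    downstream_exon_end = mc$downExonEnd,
    host_gene = mc$hostGene,
    flanking_constitutive = mc$flankingConstitutive)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GTF annotation ----

#' Read gene models from a GTF file
#'
#' Parses `gene`, `transcript`, `exon` and `CDS` features (via
#' `rtracklayer::import`) into [GeneModel-class] objects. CDS bounds are
#' re-expressed in transcript coordinates. Per-exon role flags are taken
#' from the attribute named by `roleAttribute` (values
#' constitutive/cassette/other) and default to `other`; a gene-level
#' `expressed` attribute (TRUE/FALSE) defaults to `TRUE`.
#'
#' @param path path to a GTF file.
#' @param roleAttribute name of the exon attribute carrying the role flag.
#' @return list of [GeneModel-class] objects.
#' @export
readAnnotationGtf <- function(path, roleAttribute = "exon_role") {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  geneIds <- unique(mc$gene_id[!is.na(mc$gene_id)])
  models <- vector("list", length(geneIds))
  for (gi in seq_along(geneIds)) {
    g <- geneIds[gi]
    rows <- which(mc$gene_id == g)
    expressed <- TRUE
    if (!is.null(mc$expressed)) {
      ge <- mc$expressed[rows][type[rows] == "gene"]
      ge <- ge[!is.na(ge)]
      if (length(ge)) expressed <- as.logical(ge[1L])
    }
    txIds <- unique(mc$transcript_id[rows])
    txIds <- txIds[!is.na(txIds)]
    txs <- list()
    for (t in txIds) {
      trows <- rows[!is.na(mc$transcript_id[rows]) & mc$transcript_id[rows] == t]
      exrows <- trows[type[trows] == "exon"]
      if (!length(exrows))
        stop("transcript ", t, " has no exon features")
      ex <- BiocGenerics::sort(GenomicRanges::granges(gr[exrows]))
      role <- rep("other", length(ex))
      if (!is.null(mc[[roleAttribute]])) {
        r <- mc[[roleAttribute]][exrows][order(GenomicRanges::start(gr[exrows]))]
        role[!is.na(r)] <- r[!is.na(r)]
      }
      cs <- NA_integer_; ce <- NA_integer_
      cdsrows <- trows[type[trows] == "CDS"]
      if (length(cdsrows)) {
        cds <- BiocGenerics::sort(GenomicRanges::granges(gr[cdsrows]))
        txTmp <- TranscriptModel(t, g, ex, reference = FALSE)
        inEx <- IRanges::overlapsAny(cds, ex, type = "within", ignore.strand = FALSE)
        if (!all(inEx))
          stop("CDS not contained in exons for transcript ", t)
        tpos <- unlist(lapply(seq_along(cds), function(i)
          c(genomicToTranscript(txTmp, GenomicRanges::start(cds)[i]),
            genomicToTranscript(txTmp, GenomicRanges::end(cds)[i]))))
        cs <- min(tpos); ce <- max(tpos)
        if (ce - cs + 1L != sum(GenomicRanges::width(cds)))
          stop("CDS pieces are not contiguous in transcript ", t)
      }
      txs[[length(txs) + 1L]] <- TranscriptModel(
        t, g, ex, cdsStart = cs, cdsEnd = ce, exonRole = role,
        reference = FALSE)
    }
    models[[gi]] <- GeneModel(g, txs, expressed = expressed)
  }
  models
}

#' Project the CDS of a coding transcript to genomic ranges
#' @param tx a coding [TranscriptModel-class]
#' @return `GRanges` of the CDS pieces.
#' @export
cdsGenomicRanges <- function(tx) {
  if (!isCoding(tx)) stop("transcript ", tx@transcriptId, " is non-coding")
  transcriptToGenomic(tx, tx@cdsStart, tx@cdsEnd)
}

#' Write gene models as GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` rows via
#' `rtracklayer::export`; exon roles and gene expression flags are
#' written as attributes so that [readAnnotationGtf()] round-trips.
#'
#' @param models list of [GeneModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationGtf <- function(models, path) {
  rows <- list()
  addRow <- function(gr, type, gene, tx = NA_character_,
                     role = NA_character_, expressed = NA,
                     phase = NA_integer_) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "clipSpliceMap", type = type, phase = phase,
      gene_id = gene, transcript_id = tx, exon_role = role,
      expressed = as.character(expressed))
    rows[[length(rows) + 1L]] <<- gr
  }
  for (gm in models) {
    addRow(gm@span, "gene", gm@geneId, expressed = gm@expressed)
    for (tx in gm@transcripts) {
      addRow(range(tx@exons), "transcript", gm@geneId, tx@transcriptId)
      for (i in seq_along(tx@exons))
        addRow(tx@exons[i], "exon", gm@geneId, tx@transcriptId,
               role = tx@exonRole[i])
      if (isCoding(tx)) {
        cds <- cdsGenomicRanges(tx)
        ## transcript-order pieces for phase bookkeeping
        ord <- if (as.character(GenomicRanges::strand(cds))[1L] == "-")
          rev(seq_along(cds)) else seq_along(cds)
        cum <- 0L
        for (i in ord) {
          addRow(cds[i], "CDS", gm@geneId, tx@transcriptId,
                 phase = (3L - cum %% 3L) %% 3L)
          cum <- cum + GenomicRanges::width(cds)[i]
        }
      }
    }
  }
  all <- combineGRanges(rows)
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

## ---- region classification ----

#' Classify clusters by genomic region
#'
#' Assigns each cluster exactly one label among `cds`, `5utr`, `3utr`,
#' `ncrna`, `intron`, `intergenic`. Overlap means at least one shared
#' base on the same strand; when a cluster overlaps several feature
#' types the precedence is cds > 5utr > 3utr > ncrna > intron >
#' intergenic, across all overlapping transcripts. `ncrna` marks exons of
#' transcripts without an annotated CDS.
#'
#' @param clusters `GRanges` of clusters (or tags).
#' @param models list of [GeneModel-class].
#' @return factor of labels, parallel to `clusters`.
#' @export
classifyClusterRegions <- function(clusters, models) {
  feats <- list(cds = list(), `5utr` = list(), `3utr` = list(),
                ncrna = list(), intron = list())
  for (gm in models) {
    for (tx in gm@transcripts) {
      ex <- tx@exons
      txrange <- range(ex)
      introns <- GenomicRanges::setdiff(txrange, ex)
      if (length(introns))
        feats$intron[[length(feats$intron) + 1L]] <- introns
      if (isCoding(tx)) {
        L <- transcriptLength(tx)
        feats$cds[[length(feats$cds) + 1L]] <-
          transcriptToGenomic(tx, tx@cdsStart, tx@cdsEnd)
        if (tx@cdsStart > 1L)
          feats$`5utr`[[length(feats$`5utr`) + 1L]] <-
            transcriptToGenomic(tx, 1L, tx@cdsStart - 1L)
        if (tx@cdsEnd < L)
          feats$`3utr`[[length(feats$`3utr`) + 1L]] <-
            transcriptToGenomic(tx, tx@cdsEnd + 1L, L)
      } else {
        feats$ncrna[[length(feats$ncrna) + 1L]] <- ex
      }
    }
  }
  lv <- c("cds", "5utr", "3utr", "ncrna", "intron", "intergenic")
  labels <- rep("intergenic", length(clusters))
  for (f in rev(setdiff(lv, "intergenic"))) {   # low precedence first
    if (!length(feats[[f]])) next
    fg <- combineGRanges(feats[[f]])
    hit <- IRanges::overlapsAny(clusters, fg, ignore.strand = FALSE)
    labels[hit] <- f
  }
  factor(labels, levels = lv)
}
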