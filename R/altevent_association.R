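## Association of CLIP clusters with alternative-splicing events and
## category enrichment against a cluster-relocation permutation null.

#' Association region of an event
#'
#' The contiguous genomic union upstream exon + upstream intron + event
#' + downstream intron + downstream exon: a cluster anywhere in this
#' block counts as associated with the event (the event itself or its
#' immediate flanking introns/exons).
#'
#' @param events `GRanges` from [altEvents()].
#' @return `GRanges` of association regions (same order and strand;
#'   `eventId` and `category` carried over).
#' @export
associationRegions <- function(events) {
  if (!length(events)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(eventId = character(),
                                                  category = character())
    return(out)
  }
  mc <- S4Vectors::mcols(events)
  lo <- pmin(mc$upExonStart, mc$downExonStart, GenomicRanges::start(events))
  hi <- pmax(mc$upExonEnd, mc$downExonEnd, GenomicRanges::end(events))
  GenomicRanges::GRanges(GenomicRanges::seqnames(events),
                         IRanges::IRanges(lo, hi),
                         strand = GenomicRanges::strand(events),
                         eventId = mc$eventId, category = mc$category)
}

#' Associate clusters with events
#'
#' An event is associated when at least one cluster shares at least one
#' base and the strand with its association region. A cluster may
#' support many events and vice versa; an event supported by several
#' clusters still counts once.
#'
#' @param clusters cluster `GRanges`.
#' @param events event `GRanges` from [altEvents()].
#' @return `DataFrame` with columns `eventId`, `category`, `associated`
#'   and `supportingClusters` (an integer `List` of cluster indices).
#' @export
associateClusters <- function(clusters, events) {
  regions <- associationRegions(events)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    regions, clusters, ignore.strand = FALSE))
  supp <- split(S4Vectors::subjectHits(hits),
                factor(S4Vectors::queryHits(hits),
                       levels = seq_along(regions)))
  S4Vectors::DataFrame(
    eventId = S4Vectors::mcols(regions)$eventId,
    category = S4Vectors::mcols(regions)$category,
    associated = lengths(supp) > 0L,
    supportingClusters = IRanges::IntegerList(unname(supp)))
}

#' Count associated events per category
#'
#' @param records `DataFrame` from [associateClusters()].
#' @return named integer vector over all six event categories.
#' @export
countByCategory <- function(records) {
  cats <- altEventCategories()
  tab <- table(factor(records$category[records$associated], levels = cats))
  out <- as.integer(tab)
  names(out) <- cats
  out
}

#' Permutation null for cluster-event association
#'
#' Per trial, every cluster is relocated -- preserving its length and
#' strand -- to a uniformly random position within the transcribed span
#' of a uniformly chosen expressed gene on the same strand; events are
#' then re-associated and counted per category. Returns the mean and
#' sample (n-1) standard deviation over trials.
#'
#' @param clusters cluster `GRanges`.
#' @param events event `GRanges`.
#' @param models list of [GeneModel-class] (or a `GRanges` of gene spans
#'   with an `expressed` metadata column).
#' @param nTrials number of random trials (default 100).
#' @param seed integer seed.
#' @return list of class `PermutationNull` with `expectedMean`,
#'   `expectedSd` (named over categories), `nTrials`, `trialCounts`
#'   (matrix), `seed`.
#' @export
permutationNull <- function(clusters, events, models, nTrials = 100L,
                            seed = 1L) {
  spans <- if (is(models, "GRanges")) models else {
    combineGRanges(lapply(models, function(gm) {
      sp <- gm@span
      S4Vectors::mcols(sp)$expressed <- gm@expressed
      sp
    }))
  }
  if (!is.null(S4Vectors::mcols(spans)$expressed))
    spans <- spans[S4Vectors::mcols(spans)$expressed]
  if (!length(spans)) stop("no expressed gene spans available")
  regions <- associationRegions(events)
  cats <- altEventCategories()
  cw <- GenomicRanges::width(clusters)
  cstr <- as.character(GenomicRanges::strand(clusters))
  sw <- GenomicRanges::width(spans)
  sstr <- as.character(GenomicRanges::strand(spans))
  if (any(cw > max(sw)))
    stop("a cluster is longer than every gene span; cannot relocate")
  byStrand <- lapply(c("+", "-"), function(st) which(sstr == st))
  names(byStrand) <- c("+", "-")
  counts <- matrix(0L, nrow = nTrials, ncol = length(cats),
                   dimnames = list(NULL, cats))
  withSeed(seed, {
    for (tr in seq_len(nTrials)) {
      newStart <- integer(length(clusters))
      newChrom <- character(length(clusters))
      for (st in c("+", "-")) {
        idx <- which(cstr == st)
        if (!length(idx)) next
        cand <- byStrand[[st]]
        if (!length(cand))
          stop("no expressed gene on strand ", st, " to relocate clusters")
        gi <- cand[sample.int(length(cand), length(idx), replace = TRUE)]
        room <- sw[gi] - cw[idx]
        if (any(room < 0))
          stop("a cluster is longer than a sampled gene span")
        newStart[idx] <- GenomicRanges::start(spans)[gi] +
          floor(stats::runif(length(idx)) * (room + 1))
        newChrom[idx] <- as.character(GenomicRanges::seqnames(spans))[gi]
      }
      moved <- GenomicRanges::GRanges(
        newChrom, IRanges::IRanges(newStart, width = cw), strand = cstr)
      hits <- suppressWarnings(GenomicRanges::findOverlaps(
        regions, moved, ignore.strand = FALSE))
      assoc <- unique(S4Vectors::queryHits(hits))
      tab <- table(factor(S4Vectors::mcols(regions)$category[assoc],
                          levels = cats))
      counts[tr, ] <- as.integer(tab)
    }
  })
  structure(list(
    expectedMean = colMeans(counts),
    expectedSd = if (nTrials >= 2L) apply(counts, 2L, stats::sd)
                 else stats::setNames(rep(NA_real_, length(cats)), cats),
    nTrials = as.integer(nTrials), trialCounts = counts,
    seed = as.integer(seed)), class = "PermutationNull")
}

#' Category enrichment Z-scores
#'
#' `z = (observed - expected_mean) / expected_sd`; when the permutation
#' standard deviation is zero or undefined the Z-score is reported as
#' `NA` (never a division by zero).
#'
#' @param observed named counts from [countByCategory()].
#' @param null a [permutationNull()] result.
#' @return data.frame with columns `category`, `observed`,
#'   `expected_mean`, `expected_sd`, `z`, `n_trials`.
#' @export
zScores <- function(observed, null) {
  cats <- altEventCategories()
  obs <- observed[cats]
  mu <- null$expectedMean[cats]
  sdv <- null$expectedSd[cats]
  z <- ifelse(!is.na(sdv) & sdv > 0, (obs - mu) / sdv, NA_real_)
  data.frame(category = cats, observed = as.integer(obs),
             expected_mean = as.numeric(mu), expected_sd = as.numeric(sdv),
             z = as.numeric(z), n_trials = null$nTrials,
             row.names = NULL)
}

#' Select associated cassette events flanked by constitutive exons
#'
#' The event set feeding the normalized complexity map: cassette-exon
#' category, associated with at least one cluster, and flanked by
#' constitutive exons on both sides.
#'
#' @param records `DataFrame` from [associateClusters()].
#' @param events event `GRanges`.
#' @return filtered event `GRanges`.
#' @export
selectFlankedCassetteEvents <- function(records, events) {
  mc <- S4Vectors::mcols(events)
  assoc <- records$eventId[records$associated]
  keep <- mc$category == "cassette_exon" &
    mc$eventId %in% assoc & mc$flankingConstitutive
  events[keep]
}
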