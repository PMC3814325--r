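## CLIP cluster calling: deduplication, overlap-chaining into candidate
## clusters, exact two-library binomial enrichment scoring and BH FDR.

#' Remove duplicate tags
#'
#' Keeps at most one tag per (chrom, start, end, strand); the result is
#' independent of input order (sorted output) and the operation is
#' idempotent.
#'
#' @param tags `GRanges` of tags.
#' @return deduplicated, sorted `GRanges`.
#' @export
deduplicateTags <- function(tags) {
  if (!length(tags)) return(tags)
  s <- BiocGenerics::sort(tags, ignore.strand = FALSE)
  key <- paste(GenomicRanges::seqnames(s), GenomicRanges::start(s),
               GenomicRanges::end(s), GenomicRanges::strand(s))
  s[!duplicated(key)]
}

#' Library statistics for enrichment scoring
#' @param nClipUnique,nControlUnique unique-tag counts; both must be
#'   positive.
#' @return list of class `LibraryStats`.
#' @export
libraryStats <- function(nClipUnique, nControlUnique) {
  stopifnot(nClipUnique > 0, nControlUnique > 0)
  structure(list(nClipUnique = as.numeric(nClipUnique),
                 nControlUnique = as.numeric(nControlUnique)),
            class = "LibraryStats")
}

#' Build candidate clusters from deduplicated CLIP tags
#'
#' Same-strand, same-chromosome tags whose intervals share at least one
#' base (chained transitively) are merged; abutting half-open BED
#' intervals share no base and stay separate. The cluster interval is
#' the union of its member tags, `clipCount` the number of members,
#' `peakDepth` the maximum simultaneous base-level tag coverage.
#' Candidates with `peakDepth < minDepth` are dropped.
#' `controlCount` is the number of control tags overlapping the final
#' cluster extent on the same strand (the control library is used as a
#' background estimator, not clustered itself).
#'
#' @param clipTags deduplicated CLIP tag `GRanges`.
#' @param controlTags deduplicated control tag `GRanges`.
#' @param minDepth minimum peak coverage depth (default 2: singleton
#'   tags never form a cluster).
#' @return `GRanges` of candidate clusters with metadata columns
#'   `clipCount`, `controlCount`, `peakDepth`.
#' @export
buildClusters <- function(clipTags, controlTags, minDepth = 2L) {
  if (!length(clipTags))
    stop("empty CLIP tag set: clusters are built from CLIP tags")
  stopifnot(minDepth >= 1L)
  cl <- GenomicRanges::reduce(clipTags, min.gapwidth = 0L,
                              ignore.strand = FALSE)
  S4Vectors::mcols(cl)$clipCount <-
    GenomicRanges::countOverlaps(cl, clipTags, ignore.strand = FALSE)
  ## peak depth via strand-wise coverage
  pd <- integer(length(cl))
  for (st in c("+", "-")) {
    onStrand <- as.character(GenomicRanges::strand(cl)) == st
    if (!any(onStrand)) next
    cov <- GenomicRanges::coverage(
      clipTags[as.character(GenomicRanges::strand(clipTags)) == st])
    sub <- cl[onStrand]
    for (chr in unique(as.character(GenomicRanges::seqnames(sub)))) {
      onChr <- as.character(GenomicRanges::seqnames(sub)) == chr
      if (!chr %in% names(cov)) next
      rle <- cov[[chr]]
      v <- IRanges::Views(rle,
                          GenomicRanges::start(sub)[onChr],
                          pmin(GenomicRanges::end(sub)[onChr], length(rle)))
      idx <- which(onStrand)[onChr]
      pd[idx] <- IRanges::viewMaxs(v)
    }
  }
  S4Vectors::mcols(cl)$peakDepth <- pd
  cl <- cl[pd >= minDepth]
  S4Vectors::mcols(cl)$controlCount <- suppressWarnings(
    GenomicRanges::countOverlaps(cl, controlTags, ignore.strand = FALSE))
  BiocGenerics::sort(cl, ignore.strand = TRUE)
}

#' Score cluster enrichment: fold change and exact binomial p-value
#'
#' With `c` CLIP and `k` control tags in a cluster and unique library
#' sizes `N_clip`, `N_ctrl`, the fold enrichment is
#' `((c + 0.5)/N_clip) / ((k + 0.5)/N_ctrl)` (0.5 pseudocount on both
#' rates) and the p-value is the one-sided tail `P(X >= c)` with
#' `X ~ Binomial(c + k, pi)`, `pi = N_clip/(N_clip + N_ctrl)` -- the
#' exact conditional two-library test.
#'
#' @param clipCount,controlCount per-cluster tag counts (vectorized).
#' @param stats a [libraryStats()] object.
#' @return data.frame with columns `fold`, `p`.
#' @export
scoreCluster <- function(clipCount, controlCount, stats) {
  stopifnot(inherits(stats, "LibraryStats"))
  if (any(clipCount < 1L))
    stop("clipCount must be >= 1: clusters are built from CLIP tags")
  if (any(controlCount < 0L)) stop("controlCount must be >= 0")
  fold <- ((clipCount + 0.5) / stats$nClipUnique) /
    ((controlCount + 0.5) / stats$nControlUnique)
  pi <- stats$nClipUnique / (stats$nClipUnique + stats$nControlUnique)
  p <- stats::pbinom(clipCount - 1L, clipCount + controlCount, pi,
                     lower.tail = FALSE)
  data.frame(fold = fold, p = pmin(p, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), capped at
#' 1 and invariant under input permutation.
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values, parallel to `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Call CLIP clusters against a control library
#'
#' Composes [deduplicateTags()], [buildClusters()], [scoreCluster()] and
#' [bhAdjust()]: clusters with `q <= alpha` are flagged significant.
#' Output is sorted by chromosome and start.
#'
#' @param clipTags,controlTags tag `GRanges` (both non-empty).
#' @param minDepth minimum peak depth for a candidate cluster.
#' @param alpha FDR threshold (default 0.05).
#' @return `GRanges` of clusters with metadata `clipCount`,
#'   `controlCount`, `peakDepth`, `fold`, `p`, `q`, `significant`.
#' @export
callClusters <- function(clipTags, controlTags, minDepth = 2L,
                         alpha = 0.05) {
  if (!length(clipTags)) stop("empty CLIP library")
  if (!length(controlTags)) stop("empty control library")
  clip <- deduplicateTags(clipTags)
  ctrl <- deduplicateTags(controlTags)
  stats <- libraryStats(length(clip), length(ctrl))
  cl <- buildClusters(clip, ctrl, minDepth = minDepth)
  if (!length(cl)) {
    S4Vectors::mcols(cl)$fold <- numeric(0)
    S4Vectors::mcols(cl)$p <- numeric(0)
    S4Vectors::mcols(cl)$q <- numeric(0)
    S4Vectors::mcols(cl)$significant <- logical(0)
    return(cl)
  }
  sc <- scoreCluster(S4Vectors::mcols(cl)$clipCount,
                     S4Vectors::mcols(cl)$controlCount, stats)
  S4Vectors::mcols(cl)$fold <- sc$fold
  S4Vectors::mcols(cl)$p <- sc$p
  S4Vectors::mcols(cl)$q <- bhAdjust(sc$p)
  S4Vectors::mcols(cl)$significant <- S4Vectors::mcols(cl)$q <= alpha
  BiocGenerics::sort(cl, ignore.strand = TRUE)
}

#' Write a cluster table as TSV (plus BED6 of significant clusters)
#'
#' The BED score is `min(1000, round(-10 * log10(q)))`.
#'
#' @param clusters `GRanges` from [callClusters()].
#' @param path output TSV path.
#' @param bedPath optional BED6 path for significant clusters.
#' @param provenance optional comment line appended to the TSV.
#' @return the TSV path, invisibly.
#' @export
writeClusterTable <- function(clusters, path, bedPath = NULL,
                              provenance = NULL) {
  mc <- S4Vectors::mcols(clusters)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    strand = as.character(GenomicRanges::strand(clusters)),
    clip_count = mc$clipCount, control_count = mc$controlCount,
    peak_depth = mc$peakDepth, fold = mc$fold, p = mc$p, q = mc$q,
    significant = mc$significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(provenance))
    cat("# ", provenance, "\n", sep = "", file = path, append = TRUE)
  if (!is.null(bedPath)) {
    sig <- clusters[mc$significant]
    S4Vectors::mcols(sig)$tagId <- sprintf("cluster_%05d", seq_along(sig))
    S4Vectors::mcols(sig)$score <-
      pmin(1000, round(-10 * log10(S4Vectors::mcols(sig)$q)))
    writeTagsBed(sig, bedPath)
  }
  invisible(path)
}
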