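## Normalized complexity maps: per-offset fraction of events with tag
## coverage, anchored at exon boundaries, with a randomized
## constitutive-exon control and peak calling on the exceedance.

#' @noRd
strandCoverage <- function(tags) {
  lapply(stats::setNames(c("+", "-"), c("+", "-")), function(st)
    GenomicRanges::coverage(
      tags[as.character(GenomicRanges::strand(tags)) == st]))
}

## coverage values over [lo, hi] on one chromosome; zero outside contig
#' @noRd
sliceCoverage <- function(cov, chrom, lo, hi) {
  out <- integer(hi - lo + 1L)
  if (!chrom %in% names(cov)) return(out)
  rle <- cov[[chrom]]
  s <- max(lo, 1L); e <- min(hi, length(rle))
  if (s > e) return(out)
  out[(s - lo + 1L):(e - lo + 1L)] <- as.integer(S4Vectors::window(rle, s, e))
  out
}

#' Binary coverage indicator around an event anchor
#'
#' `indicator[d] = 1` iff at least one same-strand tag covers the base
#' at transcript-oriented offset `d` from the anchor boundary (positive
#' offsets run toward the transcript 3' end; offset 0 is the terminal
#' exonic base at the splice site). Offsets beyond the contig are 0.
#'
#' @param tags tag `GRanges`.
#' @param event a single event (`GRanges` of length 1 from
#'   [altEvents()]).
#' @param anchor one of the four cassette-map anchors (see
#'   [anchorPositions()]).
#' @param window half-window in nt (default 500).
#' @return named integer 0/1 vector over offsets `-window..window`.
#' @export
eventCoverageIndicator <- function(tags, event, anchor, window = 500L) {
  stopifnot(length(event) == 1L)
  ap <- anchorPositions(event, anchor)
  cov <- strandCoverage(tags)[[ap$strand]]
  v <- sliceCoverage(cov, ap$chrom, ap$pos - window, ap$pos + window)
  if (ap$sign < 0L) v <- rev(v)
  ind <- as.integer(v > 0L)
  names(ind) <- as.character(seq(-window, window))
  ind
}

#' Normalized complexity profile
#'
#' `value(d)` is the fraction of events whose coverage indicator at
#' offset `d` is 1; each event contributes at most 1 at each offset
#' regardless of its tag count, which is the complexity normalization
#' (duplicating one event's tags never changes the profile).
#'
#' @param tags tag `GRanges`.
#' @param events event `GRanges` (non-empty).
#' @param anchor anchor name.
#' @param window half-window in nt.
#' @return list of class `ComplexityProfile` with `anchor`, `offsets`,
#'   `values` (in `[0, 1]`), `counts`, `nEvents`, `window`.
#' @export
normalizedComplexity <- function(tags, events, anchor, window = 500L) {
  if (!length(events)) stop("empty event list")
  ap <- anchorPositions(events, anchor)
  covs <- strandCoverage(tags)
  counts <- integer(2L * window + 1L)
  for (i in seq_along(events)) {
    v <- sliceCoverage(covs[[ap$strand[i]]], ap$chrom[i],
                       ap$pos[i] - window, ap$pos[i] + window)
    if (ap$sign[i] < 0L) v <- rev(v)
    counts <- counts + (v > 0L)
  }
  structure(list(anchor = anchor, offsets = seq(-window, window),
                 values = counts / length(events), counts = counts,
                 nEvents = length(events), window = as.integer(window)),
            class = "ComplexityProfile")
}

#' @export
print.ComplexityProfile <- function(x, ...) {
  cat(sprintf("ComplexityProfile: anchor %s, window +-%d nt, %d events, max value %.3f\n",
              x$anchor, x$window, x$nEvents, max(x$values)))
  invisible(x)
}

#' Randomized constitutive-exon control profile
#'
#' Draws `nSets` sets of `setSize` internal constitutive exons (without
#' replacement within a set, independently across sets) from expressed
#' genes, computes the normalized complexity anchored at the exons' own
#' 3' and 5' splice sites, and returns the per-offset mean and sample
#' standard deviation across sets.
#'
#' @param tags tag `GRanges`.
#' @param models list of [GeneModel-class].
#' @param setSize exons per set (match the number of cassette events).
#' @param nSets number of random sets (default 100; at least 2 for a
#'   standard deviation).
#' @param window half-window in nt.
#' @param seed integer seed.
#' @return list of class `ControlProfile` with per-anchor (`exon_3ss`,
#'   `exon_5ss`) `mean` and `sd` vectors, plus `offsets`, `nSets`,
#'   `setSize`, `window`.
#' @export
controlProfile <- function(tags, models, setSize, nSets = 100L,
                           window = 500L, seed = 1L) {
  stopifnot(nSets >= 2L, setSize >= 1L)
  pool <- list()
  for (gm in models) {
    if (!gm@expressed) next
    for (tx in gm@transcripts) {
      ex <- tx@exons
      if (length(ex) < 3L) next
      internal <- 2:(length(ex) - 1L)
      keep <- internal[tx@exonRole[internal] == "constitutive"]
      if (!length(keep)) next
      st <- as.character(GenomicRanges::strand(ex))[1L]
      chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
      for (i in keep)
        pool[[length(pool) + 1L]] <- list(
          chrom = chrom, strand = st,
          start = GenomicRanges::start(ex)[i],
          end = GenomicRanges::end(ex)[i])
    }
  }
  if (length(pool) < setSize)
    stop("only ", length(pool), " internal constitutive exons available; ",
         "need at least setSize = ", setSize)
  covs <- strandCoverage(tags)
  n <- 2L * window + 1L
  exonIndicator <- function(e, anchorPos, sign) {
    v <- sliceCoverage(covs[[e$strand]], e$chrom,
                       anchorPos - window, anchorPos + window)
    if (sign < 0L) v <- rev(v)
    v > 0L
  }
  m3 <- matrix(0, nSets, n); m5 <- matrix(0, nSets, n)
  withSeed(seed, {
    for (s in seq_len(nSets)) {
      idx <- sample.int(length(pool), setSize)
      acc3 <- integer(n); acc5 <- integer(n)
      for (i in idx) {
        e <- pool[[i]]
        minus <- e$strand == "-"
        ## 3'ss anchor: first exonic base in transcript orientation;
        ## 5'ss anchor: last exonic base
        p3 <- if (minus) e$end else e$start
        p5 <- if (minus) e$start else e$end
        sgn <- if (minus) -1L else 1L
        acc3 <- acc3 + exonIndicator(e, p3, sgn)
        acc5 <- acc5 + exonIndicator(e, p5, sgn)
      }
      m3[s, ] <- acc3 / setSize
      m5[s, ] <- acc5 / setSize
    }
  })
  structure(list(
    anchors = list(
      exon_3ss = list(mean = colMeans(m3), sd = apply(m3, 2L, stats::sd)),
      exon_5ss = list(mean = colMeans(m5), sd = apply(m5, 2L, stats::sd))),
    offsets = seq(-window, window), nSets = as.integer(nSets),
    setSize = as.integer(setSize), window = as.integer(window),
    seed = as.integer(seed)), class = "ControlProfile")
}

#' @export
print.ControlProfile <- function(x, ...) {
  cat(sprintf("ControlProfile: %d sets of %d constitutive exons, window +-%d nt\n",
              x$nSets, x$setSize, x$window))
  invisible(x)
}

#' @noRd
controlAnchorFor <- function(anchor) {
  if (grepl("_3ss$", anchor)) "exon_3ss" else "exon_5ss"
}

#' Smoothed exceedance of a profile over its control
#'
#' `(smoothed value - smoothed control mean) / control sd`, with the
#' control sd smoothed as well and floored at half a count
#' (`0.5/setSize`) to avoid division by a degenerate zero.
#'
#' @param profile a [normalizedComplexity()] result.
#' @param control a [controlProfile()] result on the same window.
#' @param smoothing odd width of the centered moving average.
#' @return data.frame with `anchor`, `offset`, `value`, `control_mean`,
#'   `control_sd`, `exceedance`.
#' @export
profileExceedance <- function(profile, control, smoothing = 11L) {
  if (smoothing %% 2L == 0L || smoothing > 2L * profile$window + 1L)
    stop("smoothing must be odd and no wider than the window")
  if (control$window != profile$window)
    stop("profile and control were computed on different windows")
  ctrl <- control$anchors[[controlAnchorFor(profile$anchor)]]
  sv <- movingAverage(profile$values, smoothing)
  sm <- movingAverage(ctrl$mean, smoothing)
  ss <- pmax(movingAverage(ctrl$sd, smoothing), 0.5 / control$setSize)
  data.frame(anchor = profile$anchor, offset = profile$offsets,
             value = profile$values, control_mean = ctrl$mean,
             control_sd = ctrl$sd, exceedance = (sv - sm) / ss)
}

#' Call peaks on a complexity profile
#'
#' Candidate offsets are those whose smoothed exceedance over the
#' control passes `zThreshold`; within each contiguous candidate run,
#' peaks are localized on the smoothed profile value (strong binding
#' saturates the per-event indicator into flat-topped plateaus, so each
#' peak is reported at the midpoint of its near-maximal value region;
#' regions closer than `minSeparation` nt are merged).
#'
#' @inheritParams profileExceedance
#' @param zThreshold exceedance threshold (default 3).
#' @param minSeparation minimum peak separation in nt.
#' @param minRunWidth minimum width (nt) of the above-threshold run
#'   supporting a peak. A binding peak with tag-placement spread around
#'   30 nt and tags of 20-30 nt produces an above-threshold footprint of
#'   well over 100 nt, whereas chance coincidences of a handful of
#'   background tags produce only narrow spikes; the default of 50 nt
#'   (about two tag footprints) rejects those.
#' @return data.frame with `anchor`, `offset`, `value`, `control_mean`,
#'   `control_sd`, `exceedance`, sorted by offset (zero rows when no
#'   offset exceeds the threshold).
#' @export
callMapPeaks <- function(profile, control, smoothing = 11L,
                         zThreshold = 3, minSeparation = 50L,
                         minRunWidth = 50L) {
  ex <- profileExceedance(profile, control, smoothing)
  z <- ex$exceedance
  sv <- movingAverage(profile$values, smoothing)
  sm <- movingAverage(
    control$anchors[[controlAnchorFor(profile$anchor)]]$mean, smoothing)
  h <- as.integer(minSeparation)
  empty <- ex[0, , drop = FALSE]
  above <- which(z > zThreshold)
  if (!length(above)) return(empty)
  runs <- split(above, cumsum(c(1L, diff(above) != 1L)))
  runs <- runs[lengths(runs) >= minRunWidth]
  if (!length(runs)) return(empty)
  peaks <- list()
  for (run in runs) {
    a <- run[1L]; b <- run[length(run)]
    ## local maxima of the smoothed value within the run
    cand <- run[vapply(run, function(i)
      sv[i] >= max(sv[max(a, i - h):min(b, i + h)]), logical(1))]
    groups <- split(cand, cumsum(c(1L, diff(cand) > h)))
    regions <- lapply(groups, function(g) {
      i0 <- g[which.max(sv[g])]
      tol <- 0.05 * max(sv[i0] - sm[i0], 0)
      lo <- i0; while (lo > a && sv[lo - 1L] >= sv[i0] - tol) lo <- lo - 1L
      hi <- i0; while (hi < b && sv[hi + 1L] >= sv[i0] - tol) hi <- hi + 1L
      c(lo, hi, i0)
    })
    regions <- regions[order(vapply(regions, `[`, numeric(1), 1L))]
    merged <- list()
    for (r in regions) {
      last <- if (length(merged)) merged[[length(merged)]] else NULL
      if (!is.null(last) && r[1L] <= last[2L] + h) {
        last[2L] <- max(last[2L], r[2L])
        if (sv[r[3L]] > sv[last[3L]]) last[3L] <- r[3L]
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- r
    }
    for (r in merged) {
      mid <- as.integer(round((r[1L] + r[2L]) / 2))
      row <- ex[mid, , drop = FALSE]
      row$exceedance <- max(z[r[1L]:r[2L]])
      peaks[[length(peaks) + 1L]] <- row
    }
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
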