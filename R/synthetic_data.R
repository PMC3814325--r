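## Seeded generators for a toy genome/annotation, CLIP and control tag
## libraries with planted positional peaks and motifs, planted
## fold-enriched sites, noisy band intensities, and a deterministic
## multi-exon coding fixture for the AS-NMD predictor.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the package's standard study conditions: 870 genes of 11-13 exons, a
#' cassette exon in 10% of genes (87 cassette events, each flanked by
#' constitutive exons), and a CLIP library in which half of the tags are
#' uniform background and the other half pile up at four peaks around
#' cassette exons -- +100 and +400 nt downstream of the cassette 5'
#' splice site, 150 nt upstream of the cassette 3' splice site, and
#' +300 nt downstream of the upstream constitutive exon (transcript
#' orientation).
#'
#' @param n_genes number of genes (one contig per gene).
#' @param exons_per_gene integer range `c(lo, hi)`.
#' @param exon_length,intron_length integer ranges in nt.
#' @param cassette_fraction fraction of genes carrying a cassette exon;
#'   the realized count is `round(n_genes * cassette_fraction)`.
#' @param retained_intron_fraction fraction of genes carrying a
#'   retained-intron event (drawn from the non-cassette genes).
#' @param motif RNA motif (A/C/G/U) planted near peaks in the genome.
#' @param motif_prob per event-peak probability of planting the motif.
#' @param peaks data.frame with columns `anchor` (one of
#'   `upstream_exon_5ss`, `cassette_3ss`, `cassette_5ss`,
#'   `downstream_exon_3ss`), `offset` (signed nt, transcript
#'   orientation), `width` (sd of tag 5'-end placement) and `weight`
#'   (fraction of library mass).
#' @param tag_length integer range of tag lengths in nt.
#' @param clip_library_size,control_library_size tag counts.
#' @param background_fraction fraction of CLIP tags drawn uniformly over
#'   transcribed spans; peak weights plus this fraction must sum to 1.
#' @param seed default seed for generators (each generator also accepts
#'   its own `seed` argument).
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 870L,
                             exons_per_gene = c(11L, 13L),
                             exon_length = c(120L, 180L),
                             intron_length = c(8000L, 12000L),
                             cassette_fraction = 0.1,
                             retained_intron_fraction = 0.03,
                             motif = "CAGGUU",
                             motif_prob = 0.3,
                             peaks = defaultPeaks(),
                             tag_length = c(20L, 30L),
                             clip_library_size = 20000L,
                             control_library_size = 20000L,
                             background_fraction = 0.5,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              cassette_fraction = cassette_fraction,
              retained_intron_fraction = retained_intron_fraction,
              motif = toupper(motif),
              motif_prob = motif_prob,
              peaks = peaks,
              tag_length = as.integer(tag_length),
              clip_library_size = as.integer(clip_library_size),
              control_library_size = as.integer(control_library_size),
              background_fraction = background_fraction,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Default planted-peak geometry
#' @return the four-peak specification used by [simulationConfig()].
#' @export
defaultPeaks <- function() {
  data.frame(
    anchor = c("cassette_5ss", "cassette_3ss", "cassette_5ss",
               "upstream_exon_5ss"),
    offset = c(100L, -150L, 400L, 300L),
    width = c(30L, 30L, 30L, 30L),
    weight = c(0.2, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
}

#' @noRd
validateSimulationConfig <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L,
            length(cfg$exons_per_gene) == 2L, cfg$exons_per_gene[1L] >= 3L,
            cfg$exons_per_gene[1L] <= cfg$exons_per_gene[2L],
            all(cfg$exon_length >= 1L), all(cfg$intron_length >= 1L),
            cfg$cassette_fraction >= 0, cfg$cassette_fraction <= 1,
            cfg$retained_intron_fraction >= 0,
            all(cfg$tag_length >= 1L),
            cfg$clip_library_size >= 1L, cfg$control_library_size >= 1L,
            cfg$background_fraction >= 0, cfg$background_fraction <= 1)
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config seed is mandatory")
  if (!grepl("^[ACGU]+$", cfg$motif))
    stop("motif must be an RNA string over A/C/G/U")
  pk <- cfg$peaks
  if (nrow(pk)) {
    if (!all(pk$anchor %in% mapAnchors()))
      stop("unknown peak anchor(s): ",
           paste(setdiff(pk$anchor, mapAnchors()), collapse = ", "))
    if (any(pk$width <= 0)) stop("peak widths must be > 0")
    if (abs(sum(pk$weight) + cfg$background_fraction - 1) > 1e-8)
      stop("peak weights plus background_fraction must sum to 1")
    need <- 2L * max(abs(pk$offset) + pk$width)
    if (cfg$intron_length[1L] < need)
      stop("minimum intron length ", cfg$intron_length[1L],
           " would let peaks collide with exon boundaries; need >= ", need)
  }
  invisible(cfg)
}

## ---- anchors ----

#' Genomic anchor positions of cassette-exon events
#'
#' Resolves a map anchor to a genomic coordinate per event, together
#' with the orientation sign that converts transcript-oriented offsets
#' to genomic displacements (`+1` on plus-strand genes, `-1` on minus).
#' Offset 0 is the terminal exonic base at the splice site: for a 5'
#' splice-site anchor, positive offsets run into the downstream intron;
#' for a 3' splice-site anchor, negative offsets run into the upstream
#' intron.
#'
#' @param events `GRanges` event set from [altEvents()].
#' @param anchor one of `upstream_exon_5ss`, `cassette_3ss`,
#'   `cassette_5ss`, `downstream_exon_3ss`.
#' @return data.frame with columns `chrom`, `pos`, `sign`, `strand`.
#' @export
anchorPositions <- function(events, anchor) {
  anchor <- match.arg(anchor, mapAnchors())
  mc <- S4Vectors::mcols(events)
  minus <- as.character(GenomicRanges::strand(events)) == "-"
  pos <- switch(anchor,
    upstream_exon_5ss = ifelse(minus, mc$upExonStart, mc$upExonEnd),
    cassette_3ss = ifelse(minus, GenomicRanges::end(events),
                          GenomicRanges::start(events)),
    cassette_5ss = ifelse(minus, GenomicRanges::start(events),
                          GenomicRanges::end(events)),
    downstream_exon_3ss = ifelse(minus, mc$downExonEnd, mc$downExonStart))
  data.frame(chrom = as.character(GenomicRanges::seqnames(events)),
             pos = as.integer(pos),
             sign = ifelse(minus, -1L, 1L),
             strand = ifelse(minus, "-", "+"),
             stringsAsFactors = FALSE)
}

## ---- annotation generator ----

#' Generate a synthetic genome annotation with cassette-exon events
#'
#' Builds `n_genes` single-transcript coding genes, one per contig, with
#' random strands. A fixed number (`round(n_genes * cassette_fraction)`)
#' of genes carry a cassette exon in the middle of the exon chain,
#' flanked by constitutive exons; a further subset of the remaining
#' genes carry a retained-intron event (represented over its
#' exon-intron-exon block so that the event geometry keeps abutting
#' flanking introns/exons). Optionally generates the genome sequence
#' (uniform ACGT) with the configured motif planted near peak positions.
#' Deterministic for a given `(config, seed)`.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param genome logical: also generate contig sequences? (Only sensible
#'   for small configurations; sequence is not needed for cluster
#'   calling, association or complexity maps.)
#' @return list of class `ClipSimAnnotation` with elements `models`
#'   (list of [GeneModel-class]), `events` (`GRanges` from
#'   [altEvents()]), `genome` (`DNAStringSet` or `NULL`), `spans`
#'   (`GRanges` of gene spans with `geneId`), `chromLengths`, `config`.
#' @export
generateAnnotation <- function(config, seed = config$seed, genome = FALSE) {
  validateSimulationConfig(config)
  withSeed(seed, {
    ng <- config$n_genes
    flank <- 600L
    nCass <- round(ng * config$cassette_fraction)
    cassGenes <- sort(sample.int(ng, nCass))
    nonCass <- setdiff(seq_len(ng), cassGenes)
    nRet <- min(round(ng * config$retained_intron_fraction), length(nonCass))
    retGenes <- sort(sample(nonCass, nRet))
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    chromNames <- sprintf("gchr%04d", seq_len(ng))
    geneIds <- sprintf("gene%04d", seq_len(ng))

    ne <- runifInt(ng, config$exons_per_gene[1L], config$exons_per_gene[2L])
    N <- sum(ne)
    geneOf <- rep.int(seq_len(ng), ne)
    ew <- runifInt(N, config$exon_length[1L], config$exon_length[2L])
    iw <- runifInt(N, config$intron_length[1L], config$intron_length[2L])
    ## per-gene cumulative layout: exon i starts after exon i-1 plus an
    ## intron; the first exon of each gene starts at flank + 1
    step <- ew + iw
    firstIdx <- cumsum(c(1L, ne))[seq_len(ng)]
    isFirst <- seq_len(N) %in% firstIdx
    offs <- ave(ifelse(isFirst, 0L, c(0L, step[-N])), geneOf,
                FUN = cumsum)
    starts <- as.integer(flank + 1L + offs)
    ends <- starts + ew - 1L
    lastIdx <- firstIdx + ne - 1L
    chromLengths <- stats::setNames(ends[lastIdx] + flank, chromNames)

    allEx <- GenomicRanges::GRanges(chromNames[geneOf],
                                    IRanges::IRanges(starts, ends),
                                    strand = strands[geneOf])
    spansGr <- GenomicRanges::GRanges(
      chromNames, IRanges::IRanges(starts[firstIdx], ends[lastIdx]),
      strand = strands,
      geneId = geneIds, expressed = rep(TRUE, ng),
      seqinfo = GenomeInfoDb::Seqinfo(chromNames,
                                      unname(chromLengths)))

    L <- as.integer(ave(ew, geneOf, FUN = sum)[firstIdx])
    cs <- rep(12L, ng)
    ce <- cs + 3L * ((L - cs - 9L) %/% 3L) - 1L

    ## event component vectors, filled below
    nEv <- nCass + nRet
    evId <- character(nEv); evCat <- character(nEv)
    evChr <- character(nEv); evStr <- character(nEv)
    e1 <- e2 <- ux1 <- ux2 <- ui1 <- ui2 <- di1 <- di2 <- dx1 <- dx2 <-
      integer(nEv)
    evHost <- character(nEv)
    k <- 0L

    models <- vector("list", ng)
    for (g in seq_len(ng)) {
      i1 <- firstIdx[g]; i2 <- lastIdx[g]
      ex <- allEx[i1:i2]
      role <- rep("constitutive", ne[g])
      minus <- strands[g] == "-"
      st <- starts[i1:i2]; en <- ends[i1:i2]
      isCass <- g %in% cassGenes
      if (isCass) {
        i <- as.integer(ceiling(ne[g] / 2))
        role[i] <- "cassette"
        upIdx <- if (minus) i + 1L else i - 1L
        dnIdx <- if (minus) i - 1L else i + 1L
        k <- k + 1L
        evId[k] <- sprintf("cass_%04d", g); evCat[k] <- "cassette_exon"
        evChr[k] <- chromNames[g]; evStr[k] <- strands[g]
        e1[k] <- st[i]; e2[k] <- en[i]
        ux1[k] <- st[upIdx]; ux2[k] <- en[upIdx]
        ui1[k] <- if (minus) en[i] + 1L else en[upIdx] + 1L
        ui2[k] <- if (minus) st[upIdx] - 1L else st[i] - 1L
        di1[k] <- if (minus) en[dnIdx] + 1L else en[i] + 1L
        di2[k] <- if (minus) st[i] - 1L else st[dnIdx] - 1L
        dx1[k] <- st[dnIdx]; dx2[k] <- en[dnIdx]
        evHost[k] <- geneIds[g]
      }
      if (g %in% retGenes && ne[g] >= 5L) {
        j <- as.integer(ceiling(ne[g] / 2))        # block = exons j, j+1
        blockLo <- st[j]; blockHi <- en[j + 1L]
        loIdx <- j - 1L; hiIdx <- j + 2L
        upIdx <- if (minus) hiIdx else loIdx
        dnIdx <- if (minus) loIdx else hiIdx
        k <- k + 1L
        evId[k] <- sprintf("ri_%04d", g); evCat[k] <- "retained_intron"
        evChr[k] <- chromNames[g]; evStr[k] <- strands[g]
        e1[k] <- blockLo; e2[k] <- blockHi
        ux1[k] <- st[upIdx]; ux2[k] <- en[upIdx]
        ui1[k] <- if (minus) blockHi + 1L else en[loIdx] + 1L
        ui2[k] <- if (minus) st[hiIdx] - 1L else blockLo - 1L
        di1[k] <- if (minus) en[loIdx] + 1L else blockHi + 1L
        di2[k] <- if (minus) blockLo - 1L else st[hiIdx] - 1L
        dx1[k] <- st[dnIdx]; dx2[k] <- en[dnIdx]
        evHost[k] <- geneIds[g]
      }
      ## fast path: exons are sorted and disjoint by construction
      tx <- S4Vectors::new2("TranscriptModel",
                            transcriptId = sprintf("tx%04d", g),
                            geneId = geneIds[g], exons = ex,
                            cdsStart = cs[g], cdsEnd = ce[g],
                            exonRole = role, meta = list(), check = FALSE)
      models[[g]] <- S4Vectors::new2("GeneModel", geneId = geneIds[g],
                                     transcripts = list(tx),
                                     expressed = TRUE, span = spansGr[g],
                                     check = FALSE)
    }

    sel <- seq_len(k)
    events <- altEvents(evId[sel], evCat[sel], evChr[sel], evStr[sel],
                        e1[sel], e2[sel], ux1[sel], ux2[sel],
                        ui1[sel], ui2[sel], di1[sel], di2[sel],
                        dx1[sel], dx2[sel], evHost[sel],
                        rep(TRUE, k))
    if (length(events)) {
      GenomeInfoDb::seqlevels(events) <- chromNames
      suppressWarnings(GenomeInfoDb::seqinfo(events) <-
                         GenomeInfoDb::seqinfo(spansGr))
    }

    gseq <- NULL
    if (genome) {
      motifDna <- chartr("U", "T", config$motif)
      kk <- nchar(motifDna)
      rcMotif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motifDna)))
      cass <- events[S4Vectors::mcols(events)$category == "cassette_exon"]
      plantings <- list()
      if (length(cass) && nrow(config$peaks)) {
        for (p in seq_len(nrow(config$peaks))) {
          ap <- anchorPositions(cass, config$peaks$anchor[p])
          plant <- stats::runif(length(cass)) < config$motif_prob
          if (!any(plant)) next
          pos5 <- ap$pos + ap$sign * config$peaks$offset[p]
          plantings[[length(plantings) + 1L]] <- data.frame(
            chrom = ap$chrom[plant], pos5 = pos5[plant],
            sign = ap$sign[plant], stringsAsFactors = FALSE)
        }
      }
      plants <- if (length(plantings)) do.call(rbind, plantings) else NULL
      seqs <- character(ng)
      for (g in seq_len(ng)) {
        letters <- sample(c("A", "C", "G", "T"), chromLengths[g],
                          replace = TRUE)
        if (!is.null(plants)) {
          here <- plants[plants$chrom == chromNames[g], , drop = FALSE]
          for (r in seq_len(nrow(here))) {
            if (here$sign[r] > 0L) {
              ps <- here$pos5[r]; pe <- ps + kk - 1L
              if (ps >= 1L && pe <= chromLengths[g])
                letters[ps:pe] <- strsplit(motifDna, "")[[1L]]
            } else {
              pe <- here$pos5[r]; ps <- pe - kk + 1L
              if (ps >= 1L && pe <= chromLengths[g])
                letters[ps:pe] <- strsplit(rcMotif, "")[[1L]]
            }
          }
        }
        seqs[g] <- paste(letters, collapse = "")
      }
      gseq <- Biostrings::DNAStringSet(seqs)
      names(gseq) <- chromNames
    }

    structure(list(models = models, events = events, genome = gseq,
                   spans = spansGr, chromLengths = chromLengths,
                   config = config),
              class = "ClipSimAnnotation")
  })
}

#' @export
print.ClipSimAnnotation <- function(x, ...) {
  cat("ClipSimAnnotation:", length(x$models), "genes,",
      length(x$events), "alt events",
      if (is.null(x$genome)) "(no sequence)" else "(with sequence)", "\n")
  invisible(x)
}

## ---- tag libraries ----

#' @noRd
annotationSeqinfo <- function(annotation) {
  GenomeInfoDb::Seqinfo(names(annotation$chromLengths),
                        unname(annotation$chromLengths))
}

#' @noRd
buildTagRanges <- function(chrom, pos5, len, strand, gstart, gend, prefix,
                           libname, seqinfo = NULL) {
  pos5 <- pmin(pmax(pos5, gstart), gend)      # keep 5' end in the host span
  s <- ifelse(strand == "+", pos5, pos5 - len + 1L)
  e <- ifelse(strand == "+", pos5 + len - 1L, pos5)
  s <- pmax(s, gstart); e <- pmin(e, gend)
  args <- list(chrom, IRanges::IRanges(as.integer(s), as.integer(e)),
               strand = strand,
               tagId = sprintf("%s_%07d", prefix, seq_along(chrom)),
               score = rep(0, length(chrom)), library = libname)
  if (!is.null(seqinfo)) args$seqinfo <- seqinfo
  do.call(GenomicRanges::GRanges, args)
}

#' Simulate a CLIP tag library with planted positional peaks
#'
#' Each tag is, with probability `background_fraction`, a uniform draw
#' over the transcribed spans (pre-mRNA); otherwise a peak is chosen by
#' weight, a cassette event uniformly, and the tag 5' end drawn as
#' `round(Normal(anchor + oriented offset, width))` (5'-end-driven CLIP
#' chemistry: the tag body extends toward the transcript 3' end). Tags
#' take the strand of the host gene and are clipped to its span. The
#' library size is exact.
#'
#' @param annotation a `ClipSimAnnotation` from [generateAnnotation()].
#' @param seed integer seed.
#' @param size library size (default `config$clip_library_size`).
#' @return `GRanges` of tags with `library = "clip"`.
#' @export
simulateClipLibrary <- function(annotation, seed = annotation$config$seed,
                                size = annotation$config$clip_library_size) {
  cfg <- annotation$config
  pk <- cfg$peaks
  cass <- annotation$events[
    S4Vectors::mcols(annotation$events)$category == "cassette_exon"]
  if (nrow(pk) > 0L && sum(pk$weight) > 0 && length(cass) == 0L)
    stop("peak specs given but the annotation has no cassette events")
  withSeed(seed, {
    n <- as.integer(size)
    probs <- c(cfg$background_fraction, pk$weight)
    comp <- sample.int(length(probs), n, replace = TRUE, prob = probs) - 1L
    len <- runifInt(n, cfg$tag_length[1L], cfg$tag_length[2L])
    chrom <- character(n); pos5 <- integer(n); strand <- character(n)
    gstart <- integer(n); gend <- integer(n)

    spans <- annotation$spans
    sw <- GenomicRanges::width(spans)
    bg <- comp == 0L
    if (any(bg)) {
      gi <- sample.int(length(spans), sum(bg), replace = TRUE, prob = sw)
      gs <- GenomicRanges::start(spans)[gi]; ge <- GenomicRanges::end(spans)[gi]
      chrom[bg] <- as.character(GenomicRanges::seqnames(spans))[gi]
      pos5[bg] <- runifInt(sum(bg), gs, ge)
      strand[bg] <- as.character(GenomicRanges::strand(spans))[gi]
      gstart[bg] <- gs; gend[bg] <- ge
    }
    if (length(cass)) {
      hostIdx <- match(S4Vectors::mcols(cass)$hostGene,
                       S4Vectors::mcols(spans)$geneId)
      anchors <- lapply(seq_len(nrow(pk)), function(p)
        anchorPositions(cass, pk$anchor[p]))
      for (p in seq_len(nrow(pk))) {
        sel <- comp == p
        m <- sum(sel)
        if (!m) next
        evi <- sample.int(length(cass), m, replace = TRUE)
        ap <- anchors[[p]]
        mu <- ap$pos[evi] + ap$sign[evi] * pk$offset[p]
        pos5[sel] <- as.integer(round(stats::rnorm(m, mu, pk$width[p])))
        chrom[sel] <- ap$chrom[evi]
        strand[sel] <- ap$strand[evi]
        gstart[sel] <- GenomicRanges::start(spans)[hostIdx[evi]]
        gend[sel] <- GenomicRanges::end(spans)[hostIdx[evi]]
      }
    }
    buildTagRanges(chrom, pos5, len, strand, gstart, gend, "clip",
                   "clip", seqinfo = annotationSeqinfo(annotation))
  })
}

#' Simulate a control (IgG-like) tag library
#'
#' Uniform background only over transcribed spans; otherwise identical
#' tag geometry to [simulateClipLibrary()].
#'
#' @inheritParams simulateClipLibrary
#' @param size library size (default `config$control_library_size`).
#' @return `GRanges` of tags with `library = "control"`.
#' @export
simulateControlLibrary <- function(annotation,
                                   seed = annotation$config$seed,
                                   size = annotation$config$control_library_size) {
  cfg <- annotation$config
  withSeed(seed, {
    n <- as.integer(size)
    len <- runifInt(n, cfg$tag_length[1L], cfg$tag_length[2L])
    spans <- annotation$spans
    sw <- GenomicRanges::width(spans)
    gi <- sample.int(length(spans), n, replace = TRUE, prob = sw)
    gs <- GenomicRanges::start(spans)[gi]; ge <- GenomicRanges::end(spans)[gi]
    buildTagRanges(as.character(GenomicRanges::seqnames(spans))[gi],
                   runifInt(n, gs, ge), len,
                   as.character(GenomicRanges::strand(spans))[gi],
                   gs, ge, "ctrl", "control",
                   seqinfo = annotationSeqinfo(annotation))
  })
}

#' Simulate libraries with planted fold-enriched sites
#'
#' Plants `nSites` windows (one per sampled gene) at which the local
#' CLIP tag density is `fold` times the control density; outside the
#' sites the CLIP library is uniform background, and the control library
#' is uniform everywhere. Used to measure recall and empirical FDR of
#' cluster calling against known truth.
#'
#' @param annotation a `ClipSimAnnotation`.
#' @param nSites number of planted sites.
#' @param fold local CLIP/control density ratio at the sites (equal
#'   library sizes).
#' @param siteWidth site width in nt.
#' @param clipSize,controlSize library sizes.
#' @param seed integer seed.
#' @return list with `clip`, `control` (`GRanges` tag libraries) and
#'   `sites` (`GRanges` of the planted windows).
#' @export
simulateEnrichedSiteLibraries <- function(annotation, nSites = 50L,
                                          fold = 10, siteWidth = 400L,
                                          clipSize = 100000L,
                                          controlSize = 100000L,
                                          seed = annotation$config$seed) {
  cfg <- annotation$config
  spans <- annotation$spans
  L <- sum(as.numeric(GenomicRanges::width(spans)))
  R <- L / (nSites * siteWidth)
  if (fold >= R)
    stop("requested fold ", fold, " exceeds what ", nSites, " sites of ",
         siteWidth, " nt can carry in a genome of ", L, " transcribed nt")
  bg <- (R - fold) / (R - 1)
  withSeed(seed, {
    gi <- sample.int(length(spans), nSites,
                     replace = nSites > length(spans))
    gs <- GenomicRanges::start(spans)[gi]
    gw <- GenomicRanges::width(spans)[gi]
    if (any(gw < siteWidth)) stop("gene span shorter than siteWidth")
    ss <- gs + floor(stats::runif(nSites) * (gw - siteWidth + 1))
    sites <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(spans))[gi],
      IRanges::IRanges(as.integer(ss), as.integer(ss + siteWidth - 1L)),
      strand = GenomicRanges::strand(spans)[gi],
      siteId = sprintf("site_%03d", seq_len(nSites)))

    n <- as.integer(clipSize)
    len <- runifInt(n, cfg$tag_length[1L], cfg$tag_length[2L])
    isBg <- stats::runif(n) < bg
    chrom <- character(n); pos5 <- integer(n); strand <- character(n)
    gstart <- integer(n); gend <- integer(n)
    sw <- GenomicRanges::width(spans)
    if (any(isBg)) {
      bi <- sample.int(length(spans), sum(isBg), replace = TRUE, prob = sw)
      chrom[isBg] <- as.character(GenomicRanges::seqnames(spans))[bi]
      pos5[isBg] <- runifInt(sum(isBg), GenomicRanges::start(spans)[bi],
                             GenomicRanges::end(spans)[bi])
      strand[isBg] <- as.character(GenomicRanges::strand(spans))[bi]
      gstart[isBg] <- GenomicRanges::start(spans)[bi]
      gend[isBg] <- GenomicRanges::end(spans)[bi]
    }
    if (any(!isBg)) {
      si <- sample.int(nSites, sum(!isBg), replace = TRUE)
      chrom[!isBg] <- as.character(GenomicRanges::seqnames(sites))[si]
      pos5[!isBg] <- runifInt(sum(!isBg), GenomicRanges::start(sites)[si],
                              GenomicRanges::end(sites)[si])
      strand[!isBg] <- as.character(GenomicRanges::strand(sites))[si]
      gstart[!isBg] <- GenomicRanges::start(spans)[gi[si]]
      gend[!isBg] <- GenomicRanges::end(spans)[gi[si]]
    }
    clip <- buildTagRanges(chrom, pos5, len, strand, gstart, gend,
                           "clip", "clip",
                           seqinfo = annotationSeqinfo(annotation))

    m <- as.integer(controlSize)
    clen <- runifInt(m, cfg$tag_length[1L], cfg$tag_length[2L])
    ci <- sample.int(length(spans), m, replace = TRUE, prob = sw)
    cgs <- GenomicRanges::start(spans)[ci]; cge <- GenomicRanges::end(spans)[ci]
    control <- buildTagRanges(
      as.character(GenomicRanges::seqnames(spans))[ci],
      runifInt(m, cgs, cge), clen,
      as.character(GenomicRanges::strand(spans))[ci], cgs, cge,
      "ctrl", "control", seqinfo = annotationSeqinfo(annotation))
    list(clip = clip, control = control, sites = sites)
  })
}

## ---- band intensities ----

#' Simulate noisy two-band gel intensities
#'
#' Expected intensities are `ratio * total` (skipped band) and
#' `(1 - ratio) * total` (included band); multiplicative lognormal noise
#' with coefficient of variation `cv` is applied independently to each
#' band (mean-preserving parameterisation).
#'
#' @param trueSkipRatio true skipping ratio in `[0, 1]`.
#' @param totalIntensity expected total intensity of the two bands.
#' @param cv coefficient of variation of the noise (`0` = noiseless).
#' @param n number of band pairs.
#' @param seed integer seed.
#' @return data.frame with columns `skipped`, `included`.
#' @export
simulateBandIntensities <- function(trueSkipRatio, totalIntensity = 100,
                                    cv = 0.1, n = 1L, seed = 1L) {
  stopifnot(trueSkipRatio >= 0, trueSkipRatio <= 1, cv >= 0, n >= 1)
  muS <- trueSkipRatio * totalIntensity
  muI <- (1 - trueSkipRatio) * totalIntensity
  if (cv == 0)
    return(data.frame(skipped = rep(muS, n), included = rep(muI, n)))
  withSeed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    fS <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    fI <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(skipped = muS * fS, included = muI * fI)
  })
}

## ---- AS-NMD fixture ----

#' Deterministic 15-exon coding fixture for the AS-NMD predictor
#'
#' A single-gene transcript whose 7th exon is a 100-nt cassette exon
#' (length not divisible by 3). Skipping it shifts the reading frame so
#' that the first downstream stop codon falls inside the 8th exon's
#' transcript segment, far more than 50 nt upstream of the last
#' exon-exon junction -- the classic configuration of an exon-skip
#' isoform routed to nonsense-mediated decay.
#'
#' @return list with `transcript` (a [TranscriptModel-class]) and
#'   `genome` (`DNAStringSet` with the single contig).
#' @export
fusLikeFixture <- function() {
  ew <- c(120L, rep(90L, 5L), 100L, 120L, rep(90L, 6L), 150L)
  intron <- 200L
  starts <- integer(15L); starts[1L] <- 1001L
  for (i in 1:14) starts[i + 1L] <- starts[i] + ew[i] + intron
  ends <- starts + ew - 1L
  ex <- GenomicRanges::GRanges("synFUS", IRanges::IRanges(starts, ends),
                               strand = "+")
  role <- rep("constitutive", 15L); role[7L] <- "cassette"
  cs <- 10L; ce <- 1467L
  tx <- TranscriptModel("synFUS_tx", "synFUS_gene", ex,
                        cdsStart = cs, cdsEnd = ce, exonRole = role)
  L <- sum(ew)                                  # 1480
  ## transcript sequence: GGC-repeat ORF, a GTAAGC word at an in-frame
  ## position inside exon 8 (stop codon only in the shifted frame), and
  ## the annotated TAA stop at the CDS end
  tpos <- seq_len(L)
  base <- c("G", "G", "C")[((tpos - 13L) %% 3L) + 1L]
  base[1:9] <- strsplit("ACGTACGTA", "")[[1L]]
  base[10:12] <- c("A", "T", "G")
  base[673:678] <- strsplit("GTAAGC", "")[[1L]]
  base[1465:1467] <- c("T", "A", "A")
  base[1468:L] <- "C"
  txSeq <- paste(base, collapse = "")
  ## place exon sequences on the contig; introns are a fixed T-run
  contigLen <- ends[15L] + 1000L
  contig <- rep("T", contigLen)
  off <- 0L
  for (i in 1:15) {
    contig[starts[i]:ends[i]] <- base[(off + 1L):(off + ew[i])]
    off <- off + ew[i]
  }
  genome <- Biostrings::DNAStringSet(paste(contig, collapse = ""))
  names(genome) <- "synFUS"
  stopifnot(as.character(transcriptSequence(tx, genome)) == txSeq)
  list(transcript = tx, genome = genome)
}

## ---- output directory ----

#' Write a simulated data set to disk
#'
#' Writes `genome.fa` (when sequence was generated), `annotation.gtf`,
#' `clip_tags.bed`, `control_tags.bed`, `events.tsv` and a `config.txt`
#' echo, plus a `manifest.tsv` listing every file with its md5 hash.
#'
#' @param annotation a `ClipSimAnnotation`.
#' @param clip,control tag `GRanges` libraries.
#' @param dir output directory.
#' @param force overwrite an existing directory?
#' @return path to the manifest, invisibly.
#' @export
writeSimulatedData <- function(annotation, clip, control, dir,
                               force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(annotation$genome)) {
    f <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(annotation$genome, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "annotation.gtf")
  writeAnnotationGtf(annotation$models, f); files <- c(files, f)
  f <- file.path(dir, "clip_tags.bed")
  writeTagsBed(clip, f); files <- c(files, f)
  f <- file.path(dir, "control_tags.bed")
  writeTagsBed(control, f); files <- c(files, f)
  f <- file.path(dir, "events.tsv")
  writeAltEvents(annotation$events, f); files <- c(files, f)
  f <- file.path(dir, "config.txt")
  cfg <- annotation$config
  flat <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.data.frame(v))
      paste(apply(v, 1L, paste, collapse = ","), collapse = ";")
    else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(cfg), ": ", flat), f); files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mf)
}
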