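## End-to-end orchestration on synthetic data: simulate, call clusters,
## classify regions, associate with splicing events, build the
## complexity map, run motif enrichment, and write deterministic
## reports with a hashed manifest.

#' Run the full synthetic pipeline
#'
#' Simulates a data set under `config`, calls CLIP clusters against the
#' control library, classifies cluster regions, associates significant
#' clusters with alternative-splicing events (permutation Z-scores),
#' computes the four-anchor normalized complexity map with its
#' constitutive-exon control and calls map peaks, optionally runs k-mer
#' motif enrichment (requires `genome = TRUE`), and writes one TSV per
#' stage plus a manifest of md5 hashes. Each report carries a trailing
#' provenance comment (package version, seed); with a fixed seed the
#' output directory is byte-reproducible.
#'
#' @param outdir output directory.
#' @param config a [simulationConfig()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param genome simulate contig sequences and run the motif stage?
#' @param nTrials permutation trials for association Z-scores.
#' @param window,setSize,nSets,smoothing,zThreshold complexity-map
#'   parameters (`setSize` defaults to the number of cassette events).
#' @param k k-mer length for motif enrichment.
#' @param minDepth,alpha cluster-calling parameters.
#' @param force overwrite an existing output directory?
#' @param verbose log stage progress to stderr?
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(outdir, config = simulationConfig(),
                        seed = config$seed, genome = FALSE,
                        nTrials = 100L, window = 500L, setSize = NULL,
                        nSets = 100L, smoothing = 11L, zThreshold = 3,
                        k = 6L, minDepth = 2L, alpha = 0.05,
                        force = FALSE, verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose)
    message(sprintf("[clipSpliceMap %5.1fs] ",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- function(stage) sprintf(
    "clipSpliceMap %s | stage=%s | seed=%d",
    as.character(utils::packageVersion("clipSpliceMap")), stage, seed)
  writeReport <- function(df, file, stage) {
    path <- file.path(outdir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat("# ", prov(stage), "\n", sep = "", file = path, append = TRUE)
    path
  }
  files <- character()

  say("simulating annotation (", config$n_genes, " genes)")
  ann <- generateAnnotation(config, seed = seed, genome = genome)
  clip <- simulateClipLibrary(ann, seed = seed + 1L)
  ctrl <- simulateControlLibrary(ann, seed = seed + 2L)
  writeSimulatedData(ann, clip, ctrl, file.path(outdir, "simulated"),
                     force = force)
  files <- c(files, list.files(file.path(outdir, "simulated"),
                               full.names = TRUE))

  say("calling clusters (", length(clip), " CLIP / ", length(ctrl),
      " control tags)")
  clusters <- callClusters(clip, ctrl, minDepth = minDepth, alpha = alpha)
  sig <- clusters[S4Vectors::mcols(clusters)$significant]
  files <- c(files, writeClusterTable(
    clusters, file.path(outdir, "clusters.tsv"),
    bedPath = file.path(outdir, "clusters_significant.bed"),
    provenance = prov("call-clusters")),
    file.path(outdir, "clusters_significant.bed"))

  say("classifying regions for ", length(clusters), " clusters (",
      length(sig), " significant)")
  regions <- classifyClusterRegions(clusters, ann$models)
  regionTab <- as.data.frame(table(region = regions))
  names(regionTab) <- c("region", "n_clusters")
  regionTab$fraction <- regionTab$n_clusters / max(1L, length(clusters))
  files <- c(files, writeReport(regionTab, "regions.tsv", "classify-regions"))

  say("associating clusters with ", length(ann$events), " events")
  records <- associateClusters(sig, ann$events)
  null <- permutationNull(sig, ann$events, ann$models,
                          nTrials = nTrials, seed = seed + 3L)
  enrich <- zScores(countByCategory(records), null)
  enrich$seed <- seed + 3L
  assocDf <- data.frame(event_id = records$eventId,
                        category = records$category,
                        associated = records$associated,
                        n_supporting = lengths(records$supportingClusters))
  files <- c(files, writeReport(assocDf, "association.tsv", "associate"),
             writeReport(enrich, "category_enrichment.tsv", "associate"))

  say("building complexity map")
  mapEvents <- selectFlankedCassetteEvents(records, ann$events)
  profiles <- NULL; peaks <- NULL
  if (length(mapEvents)) {
    if (is.null(setSize)) setSize <- length(mapEvents)
    control <- controlProfile(clip, ann$models, setSize = setSize,
                              nSets = nSets, window = window,
                              seed = seed + 4L)
    profiles <- lapply(mapAnchors(), function(a)
      normalizedComplexity(clip, mapEvents, a, window = window))
    names(profiles) <- mapAnchors()
    mapDf <- do.call(rbind, lapply(profiles, profileExceedance,
                                   control = control,
                                   smoothing = smoothing))
    peaks <- do.call(rbind, lapply(profiles, callMapPeaks,
                                   control = control,
                                   smoothing = smoothing,
                                   zThreshold = zThreshold))
    files <- c(files, writeReport(mapDf, "complexity_map.tsv", "rnamap"),
               writeReport(peaks, "map_peaks.tsv", "rnamap"))
  } else say("no flanked associated cassette events; map skipped")

  motifs <- NULL
  if (genome && length(sig)) {
    say("motif enrichment over ", length(sig), " cluster sequences")
    seqs <- extractClusterSequences(sig, ann$genome)
    seqs <- seqs[Biostrings::width(seqs) >= k]
    if (length(seqs)) {
      bg <- makeBackground(seqs, nPerTarget = 10L, mode = "shuffle",
                           seed = seed + 5L)
      motifs <- kmerEnrichment(seqs, bg, k = k)
      files <- c(files, writeReport(motifs, "motifs.tsv", "motifs"))
    }
  }

  say("demonstrating AS-NMD call on the cassette fixture")
  fx <- fusLikeFixture()
  skipped <- skipExon(fx$transcript, 7L)
  nmd <- predictNmd(skipped, transcriptSequence(skipped, fx$genome))
  nmdDf <- data.frame(
    transcript = skipped@transcriptId, skipped_exon = 7L,
    frameshift = nmd$frameshift, ptc_position = nmd$ptcPosition,
    last_junction = nmd$lastJunctionPosition,
    ptc_to_last_junction = nmd$ptcToLastJunction, nmd = nmd$nmd)
  files <- c(files, writeReport(nmdDf, "nmd_report.tsv", "nmd"))

  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done: ", length(files), " report files")
  invisible(list(annotation = ann, clusters = clusters, regions = regions,
                 association = records, enrichment = enrich,
                 profiles = profiles, mapPeaks = peaks, motifs = motifs,
                 nmd = nmd))
}
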