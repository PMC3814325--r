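## k-mer motif enrichment of cluster sequences over a randomized
## background, with an exact binomial window test and BH FDR.

#' Extract strand-aware RNA sequences of clusters
#'
#' Plus-strand clusters are transcribed directly (T to U); minus-strand
#' clusters are reverse complemented first.
#'
#' @param clusters `GRanges`.
#' @param genome named `DNAStringSet`.
#' @return `RNAStringSet`, parallel to `clusters`.
#' @export
extractClusterSequences <- function(clusters, genome) {
  if (!length(clusters)) return(Biostrings::RNAStringSet())
  chroms <- as.character(GenomicRanges::seqnames(clusters))
  if (!all(chroms %in% names(genome)))
    stop("cluster chromosome(s) missing from genome: ",
         paste(unique(setdiff(chroms, names(genome))), collapse = ", "))
  seqs <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    contig <- genome[[chroms[i]]]
    s <- GenomicRanges::start(clusters)[i]
    e <- GenomicRanges::end(clusters)[i]
    if (s < 1L || e > length(contig))
      stop("cluster ", i, " extends beyond contig ", chroms[i])
    dna <- Biostrings::subseq(contig, s, e)
    if (as.character(GenomicRanges::strand(clusters))[i] == "-")
      dna <- Biostrings::reverseComplement(dna)
    seqs[[i]] <- Biostrings::RNAString(dna)
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- sprintf("cluster_%05d", seq_along(clusters))
  out
}

#' Select clusters with deeply covered centers
#'
#' Keeps clusters whose maximum tag depth strictly exceeds
#' `minCenterDepth` (sub-region selection for motif analysis of the most
#' strongly bound sites).
#'
#' @param clusters `GRanges` with a `peakDepth` metadata column.
#' @param minCenterDepth depth threshold (strict `>`; default 100).
#' @return filtered `GRanges` (possibly empty).
#' @export
selectHighDepthSubregions <- function(clusters, minCenterDepth = 100L) {
  pd <- S4Vectors::mcols(clusters)$peakDepth
  if (is.null(pd)) stop("clusters lack a peakDepth metadata column")
  clusters[pd > minCenterDepth]
}

#' Generate background sequences for motif enrichment
#'
#' `mode = "shuffle"` (default, self-contained): for each target
#' sequence, `nPerTarget` independent uniform permutations of its
#' letters, preserving length and mononucleotide composition.
#' `mode = "genomic"`: length-matched draws from a supplied genome at
#' uniform positions and random strands.
#'
#' @param targetSeqs `RNAStringSet` (non-empty).
#' @param nPerTarget background sequences per target.
#' @param mode `"shuffle"` or `"genomic"`.
#' @param genome named `DNAStringSet`, required for genomic mode.
#' @param seed integer seed.
#' @return `RNAStringSet` of background sequences.
#' @export
makeBackground <- function(targetSeqs, nPerTarget = 10L,
                           mode = c("shuffle", "genomic"), genome = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (!length(targetSeqs)) stop("no target sequences")
  withSeed(seed, {
    if (mode == "shuffle") {
      chars <- strsplit(as.character(targetSeqs), "")
      out <- unlist(lapply(chars, function(ch)
        vapply(seq_len(nPerTarget), function(i)
          paste(sample(ch), collapse = ""), character(1))))
      Biostrings::RNAStringSet(out)
    } else {
      if (is.null(genome)) stop("genomic background mode needs a genome")
      lens <- Biostrings::width(targetSeqs)
      clens <- vapply(seq_along(genome), function(i) length(genome[[i]]),
                      integer(1))
      out <- character(length(lens) * nPerTarget)
      k <- 0L
      for (L in rep(lens, each = nPerTarget)) {
        ok <- which(clens >= L)
        if (!length(ok)) stop("no contig long enough for length ", L)
        ci <- ok[sample.int(length(ok), 1L)]
        s <- 1L + floor(stats::runif(1) * (clens[ci] - L + 1L))
        dna <- Biostrings::subseq(genome[[ci]], s, s + L - 1L)
        if (stats::runif(1) < 0.5)
          dna <- Biostrings::reverseComplement(dna)
        k <- k + 1L
        out[k] <- as.character(Biostrings::RNAString(dna))
      }
      Biostrings::RNAStringSet(out)
    }
  })
}

#' k-mer enrichment of target sequences over background
#'
#' Counts all overlapping k-mer windows (a sequence of length `L`
#' contributes `L - k + 1` windows). For each k-mer with at least one
#' target hit: `fold = (target rate) / (background rate with a 0.5/1
#' pseudocount)` and `p` is the one-sided binomial tail
#' `P(X >= hits | n = target windows, pi = background rate)`;
#' q-values by BH over the tested k-mers.
#'
#' @param targetSeqs,backgroundSeqs `RNAStringSet`s.
#' @param k k-mer length (5 or 6).
#' @return data.frame sorted by `p` then decreasing `fold`, with
#'   columns `kmer`, `target_hits`, `target_positions`,
#'   `background_hits`, `background_positions`, `fold`, `p`, `q`.
#' @export
kmerEnrichment <- function(targetSeqs, backgroundSeqs, k = 6L) {
  if (!k %in% c(5L, 6L)) stop("k must be 5 or 6")
  if (!length(targetSeqs)) stop("no target sequences")
  if (any(Biostrings::width(targetSeqs) < k))
    stop("all target sequences must contain at least one k-mer window")
  tHits <- colSums(Biostrings::oligonucleotideFrequency(
    targetSeqs, width = k, step = 1L))
  bHits <- colSums(Biostrings::oligonucleotideFrequency(
    backgroundSeqs, width = k, step = 1L))
  tPos <- sum(pmax(Biostrings::width(targetSeqs) - k + 1L, 0L))
  bPos <- sum(pmax(Biostrings::width(backgroundSeqs) - k + 1L, 0L))
  keep <- tHits >= 1L
  kmers <- names(tHits)[keep]
  th <- as.integer(tHits[keep]); bh <- as.integer(bHits[kmers])
  piB <- (bh + 0.5) / (bPos + 1)
  fold <- (th / tPos) / piB
  p <- pmin(stats::pbinom(th - 1L, tPos, piB, lower.tail = FALSE), 1)
  q <- bhAdjust(p)
  out <- data.frame(kmer = kmers, target_hits = th,
                    target_positions = tPos, background_hits = bh,
                    background_positions = bPos, fold = fold, p = p, q = q)
  out <- out[order(out$p, -out$fold, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
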