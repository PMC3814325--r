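test_that("annotation generation is deterministic and plants the configured events", {
  cfg <- smallConfig()
  a1 <- generateAnnotation(cfg, seed = 5, genome = TRUE)
  a2 <- generateAnnotation(cfg, seed = 5, genome = TRUE)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(start(a1$events), start(a2$events))
  cass <- a1$events[mcols(a1$events)$category == "cassette_exon"]
  expect_length(cass, round(cfg$n_genes * cfg$cassette_fraction))
  expect_true(all(mcols(cass)$flankingConstitutive))
  validateAltEvents(a1$events)
  ## every cassette exon's flanks really are constitutive in the model
  for (i in seq_along(cass)) {
    gm <- a1$models[[match(mcols(cass)$hostGene[i],
                           vapply(a1$models, geneId, character(1)))]]
    tx <- transcripts(gm)[[1L]]
    ci <- which(exonRole(tx) == "cassette")
    expect_equal(exonRole(tx)[c(ci - 1L, ci + 1L)],
                 c("constitutive", "constitutive"))
  }
})

test_that("intron lengths too short for the peak geometry are rejected", {
  expect_error(smallConfig(intron_length = c(500L, 600L)),
               "collide")
})

test_that("libraries have exact size and are seed-reproducible", {
  ann <- smallAnn()
  c1 <- simulateClipLibrary(ann, seed = 2, size = 1234L)
  c2 <- simulateClipLibrary(ann, seed = 2, size = 1234L)
  expect_length(c1, 1234L)
  expect_identical(start(c1), start(c2))
  k1 <- simulateControlLibrary(ann, seed = 3, size = 777L)
  expect_length(k1, 777L)
  expect_false(identical(start(simulateControlLibrary(ann, seed = 4,
                                                      size = 777L)),
                         start(k1)))
})

test_that("background tags distribute uniformly over transcribed spans", {
  cfg <- smallConfig(background_fraction = 1, peaks = emptyPeaks())
  ann <- generateAnnotation(cfg, seed = 9)
  tags <- simulateClipLibrary(ann, seed = 10, size = 50000L)
  ## tag 5' starts per gene should follow span-width proportions
  p5 <- ifelse(as.character(strand(tags)) == "+", start(tags), end(tags))
  gene <- as.character(seqnames(tags))
  obs <- table(factor(gene, levels = as.character(seqnames(ann$spans))))
  expW <- width(ann$spans) / sum(width(ann$spans))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = expW))
  expect_gt(gof$p.value, 0.01)
})

test_that("a single planted peak puts the tag-start mode at the configured offset", {
  pk <- data.frame(anchor = "cassette_5ss", offset = 100L, width = 30L,
                   weight = 0.8)
  cfg <- smallConfig(background_fraction = 0.2, peaks = pk)
  ann <- generateAnnotation(cfg, seed = 21)
  tags <- simulateClipLibrary(ann, seed = 22, size = 20000L)
  cass <- ann$events[mcols(ann$events)$category == "cassette_exon"]
  ap <- anchorPositions(cass, "cassette_5ss")
  ## oriented offset of each tag 5' end from its chromosome's anchor
  idx <- match(as.character(seqnames(tags)), ap$chrom)
  ok <- !is.na(idx)
  p5 <- ifelse(as.character(strand(tags)) == "+", start(tags), end(tags))
  off <- (p5[ok] - ap$pos[idx[ok]]) * ap$sign[idx[ok]]
  off <- off[abs(off) <= 500]
  h <- table(cut(off, breaks = seq(-500, 500, by = 10)))
  modeCenter <- seq(-495, 495, by = 10)[which.max(h)]
  expect_lte(abs(modeCenter - 100), 10)
})

test_that("planted motifs exceed background density; probability 0 gives background only", {
  k <- 6L
  cfg0 <- smallConfig(motif_prob = 0)
  ann0 <- generateAnnotation(cfg0, seed = 31, genome = TRUE)
  nPos <- sum(width(ann0$genome) - k + 1)
  hits0 <- sum(Biostrings::vcountPattern("CAGGTT", ann0$genome)) +
    sum(Biostrings::vcountPattern("AACCTG", ann0$genome))
  ## both strands scanned: expected rate 2 * 4^-6 per window
  expect_lt(hits0, qbinom(0.999, nPos, 2 * 4^-6))

  cfg1 <- smallConfig(motif_prob = 1)
  ann1 <- generateAnnotation(cfg1, seed = 31, genome = TRUE)
  hits1 <- sum(Biostrings::vcountPattern("CAGGTT", ann1$genome)) +
    sum(Biostrings::vcountPattern("AACCTG", ann1$genome))
  nCassPeaks <- 4L * round(cfg1$n_genes * cfg1$cassette_fraction)
  expect_gte(hits1, hits0 + 0.9 * nCassPeaks)
})

test_that("per-peak library mass matches the configured weights", {
  ann <- smallAnn()   # weights .2/.1/.1/.1 + background .5
  tags <- simulateClipLibrary(ann, seed = 41, size = 20000L)
  cass <- ann$events[mcols(ann$events)$category == "cassette_exon"]
  pk <- ann$config$peaks
  counts <- integer(nrow(pk))
  p5 <- ifelse(as.character(strand(tags)) == "+", start(tags), end(tags))
  for (p in seq_len(nrow(pk))) {
    ap <- anchorPositions(cass, pk$anchor[p])
    idx <- match(as.character(seqnames(tags)), ap$chrom)
    ok <- !is.na(idx)
    off <- (p5[ok] - (ap$pos[idx[ok]] + ap$sign[idx[ok]] * pk$offset[p])) *
      ap$sign[idx[ok]]
    counts[p] <- sum(abs(off) <= 3 * pk$width[p])
  }
  ## counts share the non-background mass according to the weights
  ## (background contamination inside the windows is negligible here)
  gof <- suppressWarnings(chisq.test(counts, p = pk$weight / sum(pk$weight)))
  expect_gt(gof$p.value, 0.001)
})

test_that("band intensity simulation respects the noise model", {
  exact <- simulateBandIntensities(0.3, 100, cv = 0, n = 5, seed = 1)
  expect_equal(skippingRatio(exact$skipped, exact$included)$skipping_ratio,
               rep(0.3, 5))
  zero <- simulateBandIntensities(0, 100, cv = 0.2, n = 20, seed = 2)
  expect_true(all(zero$skipped == 0))
  noisy <- simulateBandIntensities(0.5, 100, cv = 0.1, n = 1000, seed = 3)
  r <- skippingRatio(noisy$skipped, noisy$included)$skipping_ratio
  expect_lt(abs(mean(r) - 0.5), 0.02)
})

test_that("the cassette fixture has the engineered AS-NMD geometry", {
  fx <- fusLikeFixture()
  tx <- fx$transcript
  exTx <- exonsInTranscriptOrder(tx)
  expect_length(exTx, 15L)
  expect_true(width(exTx)[7L] %% 3L != 0L)
  expect_equal(exonRole(tx)[7L], "cassette")
  ## the full-length isoform translates cleanly to its annotated stop
  seqFull <- transcriptSequence(tx, fx$genome)
  expect_identical(firstStopOracle(seqFull, cdsStart(tx)),
                   cdsEnd(tx) - 2L)
})

test_that("planted enriched sites carry the requested fold in tag mass", {
  ann <- smallAnn()
  sim <- simulateEnrichedSiteLibraries(ann, nSites = 10L, fold = 10,
                                       siteWidth = 400L,
                                       clipSize = 20000L,
                                       controlSize = 20000L, seed = 6)
  expect_length(sim$clip, 20000L)
  expect_length(sim$control, 20000L)
  cs <- countOverlaps(sim$sites, sim$clip, ignore.strand = FALSE)
  ks <- countOverlaps(sim$sites, sim$control, ignore.strand = FALSE)
  ## mean in-site clip/control ratio approximates the configured fold
  expect_gt(sum(cs) / max(1, sum(ks)), 5)
  expect_error(simulateEnrichedSiteLibraries(ann, nSites = 10L,
                                             fold = 1e6, seed = 1),
               "exceeds")
})
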