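test_that("the coverage indicator follows transcript-oriented offsets", {
  ev <- toyCassetteEvent()
  expect_true(all(eventCoverageIndicator(mkTags("chrZ", 1, 30), ev,
                                         "cassette_5ss") == 0L))
  ## cassette 5'ss anchor is the exon end (1100); a 30-nt tag starting at
  ## anchor+100 covers oriented offsets 100..129
  tag <- mkTags("chrT", 1200, 1229)
  ind <- eventCoverageIndicator(tag, ev, "cassette_5ss", window = 500)
  expect_equal(sum(ind), 30L)
  expect_equal(unname(which(ind == 1L)) - 501L, 100:129)

  ## mirrored minus-strand geometry: anchor = event start (1001);
  ## offsets 100..129 are genomic 901..872
  evm <- toyCassetteEvent("-")
  tagm <- mkTags("chrT", 872, 901, "-")
  indm <- eventCoverageIndicator(tagm, evm, "cassette_5ss", window = 500)
  expect_identical(indm, ind)
})

test_that("normalized complexity is a per-event fraction, saturated per event", {
  ev <- toyCassetteEvent()
  tag <- mkTags("chrT", 1100, 1129)   # covers offset 0 at the 5'ss
  prof <- normalizedComplexity(tag, ev, "cassette_5ss")
  expect_equal(prof$values[prof$offsets == 0], 1.0)
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  ## value * n_events is a count
  expect_true(all(abs(prof$values * prof$nEvents -
                        round(prof$values * prof$nEvents)) < 1e-9))

  ## 10 events, 3 covered at +100 -> 0.3
  evs <- altEvents(sprintf("e%02d", 1:10), rep("cassette_exon", 10),
                   "chrT", "+",
                   seq(1001, by = 10000, length.out = 10),
                   seq(1100, by = 10000, length.out = 10),
                   seq(701, by = 10000, length.out = 10),
                   seq(800, by = 10000, length.out = 10),
                   seq(801, by = 10000, length.out = 10),
                   seq(1000, by = 10000, length.out = 10),
                   seq(1101, by = 10000, length.out = 10),
                   seq(1400, by = 10000, length.out = 10),
                   seq(1401, by = 10000, length.out = 10),
                   seq(1500, by = 10000, length.out = 10),
                   sprintf("g%02d", 1:10), TRUE)
  tags3 <- mkTags("chrT", start(evs)[1:3] + 199, start(evs)[1:3] + 228)
  prof3 <- normalizedComplexity(tags3, evs, "cassette_5ss")
  expect_equal(prof3$values[prof3$offsets == 100], 0.3)

  ## duplicating one event's tags never changes the profile (normalization)
  dup <- suppressWarnings(c(tags3, rep(tags3[1L], 5L)))
  profDup <- normalizedComplexity(dup, evs, "cassette_5ss")
  expect_identical(profDup$values, prof3$values)

  ## empty tag set gives the all-zero profile
  expect_true(all(normalizedComplexity(GRanges(), evs,
                                       "cassette_5ss")$values == 0))
  expect_error(normalizedComplexity(tags3, evs[0], "cassette_5ss"), "empty")
})

test_that("reflecting the genome leaves transcript-oriented profiles unchanged", {
  ## mirror the full synthetic locus set: position x -> Lc - x + 1 on each
  ## contig, strands flipped; profiles must be identical
  ann <- smallAnn()
  clip <- simulateClipLibrary(ann, seed = 13, size = 3000L)
  Lc <- ann$chromLengths[as.character(seqnames(clip))]
  mClip <- GRanges(seqnames(clip),
                   IRanges(Lc - end(clip) + 1L, Lc - start(clip) + 1L),
                   strand = ifelse(as.character(strand(clip)) == "+", "-", "+"))
  ev <- ann$events
  Le <- ann$chromLengths[as.character(seqnames(ev))]
  mc <- mcols(ev)
  mEv <- altEvents(mc$eventId, mc$category, as.character(seqnames(ev)),
                   ifelse(as.character(strand(ev)) == "+", "-", "+"),
                   Le - end(ev) + 1L, Le - start(ev) + 1L,
                   Le - mc$upExonEnd + 1L, Le - mc$upExonStart + 1L,
                   Le - mc$upIntronEnd + 1L, Le - mc$upIntronStart + 1L,
                   Le - mc$downIntronEnd + 1L, Le - mc$downIntronStart + 1L,
                   Le - mc$downExonEnd + 1L, Le - mc$downExonStart + 1L,
                   mc$hostGene, mc$flankingConstitutive)
  cassOrig <- ev[mc$category == "cassette_exon"]
  cassMirr <- mEv[mc$category == "cassette_exon"]
  for (a in c("cassette_5ss", "cassette_3ss", "upstream_exon_5ss")) {
    p1 <- normalizedComplexity(clip, cassOrig, a)
    p2 <- normalizedComplexity(mClip, cassMirr, a)
    expect_identical(p1$values, p2$values)
  }
})

test_that("control profiles are seeded, need two sets, and demand enough exons", {
  ann <- smallAnn()
  clip <- simulateClipLibrary(ann, seed = 5, size = 3000L)
  c1 <- controlProfile(clip, ann$models, setSize = 10, nSets = 5, seed = 2)
  c2 <- controlProfile(clip, ann$models, setSize = 10, nSets = 5, seed = 2)
  expect_identical(c1$anchors$exon_3ss$mean, c2$anchors$exon_3ss$mean)
  expect_identical(c1$anchors$exon_5ss$sd, c2$anchors$exon_5ss$sd)
  expect_silent(controlProfile(clip, ann$models, setSize = 10, nSets = 2,
                               seed = 1))
  expect_error(controlProfile(clip, ann$models, setSize = 10, nSets = 1,
                              seed = 1))
  expect_error(controlProfile(clip, ann$models, setSize = 10^5, seed = 1),
               "constitutive exons")
})

test_that("peak calling rejects bad smoothing and is silent on null profiles", {
  ann <- smallAnn()
  clip <- simulateClipLibrary(ann, seed = 5, size = 3000L)
  cass <- ann$events[mcols(ann$events)$category == "cassette_exon"]
  prof <- normalizedComplexity(clip, cass, "cassette_5ss")
  ctrl <- controlProfile(clip, ann$models, setSize = length(cass),
                         nSets = 20, seed = 9)
  expect_error(callMapPeaks(prof, ctrl, smoothing = 10L), "odd")
  ## a profile identical to the control mean has no exceedance
  flat <- prof
  flat$values <- ctrl$anchors$exon_5ss$mean
  expect_equal(nrow(callMapPeaks(flat, ctrl)), 0L)
})

test_that("planted peaks are recovered at small scale with correct ordering", {
  cfg <- simulationConfig(n_genes = 60L, exons_per_gene = c(5L, 7L),
                          exon_length = c(120L, 180L),
                          intron_length = c(2000L, 3000L),
                          cassette_fraction = 0.5,
                          retained_intron_fraction = 0,
                          clip_library_size = 8000L,
                          control_library_size = 8000L)
  ann <- generateAnnotation(cfg, seed = 2)
  cass <- ann$events[mcols(ann$events)$category == "cassette_exon"]
  clip <- simulateClipLibrary(ann, seed = 3)
  ctrl <- controlProfile(clip, ann$models, setSize = length(cass),
                         nSets = 50, seed = 4)
  pk5 <- callMapPeaks(normalizedComplexity(clip, cass, "cassette_5ss"), ctrl)
  ## the two 5'ss peaks (+100, +400) both called, ordered by offset
  expect_gte(nrow(pk5), 2L)
  expect_true(!is.unsorted(pk5$offset))
  expect_lte(min(abs(pk5$offset - 100)), 20)
  expect_lte(min(abs(pk5$offset - 400)), 20)
  pk3 <- callMapPeaks(normalizedComplexity(clip, cass, "cassette_3ss"), ctrl)
  expect_lte(min(abs(pk3$offset - (-150))), 20)
})
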