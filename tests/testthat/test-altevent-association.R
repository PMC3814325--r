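test_that("association regions are the contiguous union of event components", {
  ev <- toyCassetteEvent()
  r <- associationRegions(ev)
  expect_equal(start(r), 701L)
  expect_equal(end(r), 1500L)
  ## retained-intron-style geometry uses the same rule
  ri <- altEvents("ri1", "retained_intron", "chrT", "+",
                  1001, 1400, 701, 800, 801, 1000, 1401, 1600,
                  1601, 1700, "g", TRUE)
  expect_equal(start(associationRegions(ri)), 701L)
  expect_equal(end(associationRegions(ri)), 1700L)
})

test_that("cluster-event association respects the region and the strand", {
  ev <- toyCassetteEvent()
  inExon <- mkTags("chrT", 1010, 1050)
  inUpIntron <- mkTags("chrT", 850, 890)
  beyond <- mkTags("chrT", 200, 260)            # past the flanking exon
  wrongStrand <- mkTags("chrT", 1010, 1050, "-")
  expect_true(associateClusters(inExon, ev)$associated)
  expect_true(associateClusters(inUpIntron, ev)$associated)
  expect_false(associateClusters(beyond, ev)$associated)
  expect_false(associateClusters(wrongStrand, ev)$associated)
  ## an event supported by several clusters still counts once
  rec <- associateClusters(suppressWarnings(c(inExon, inUpIntron)), ev)
  expect_equal(sum(rec$associated), 1L)
  expect_length(rec$supportingClusters[[1L]], 2L)
})

test_that("association is monotone in the cluster set", {
  ann <- smallAnn()
  clip <- simulateClipLibrary(ann, seed = 3)
  ctrl <- simulateControlLibrary(ann, seed = 4)
  cl <- callClusters(clip, ctrl)
  half <- cl[seq_len(length(cl) %/% 2)]
  a1 <- associateClusters(half, ann$events)$associated
  a2 <- associateClusters(cl, ann$events)$associated
  expect_true(all(a2[a1]))
})

test_that("category counts cover all categories and sum to associated events", {
  ev <- suppressWarnings(c(
    toyCassetteEvent(),
    altEvents(c("c2", "c3"), rep("cassette_exon", 2), "chrU", "+",
              c(2001, 9001), c(2100, 9100),
              c(1701, 8701), c(1800, 8800), c(1801, 8801), c(2000, 9000),
              c(2101, 9101), c(2400, 9400), c(2401, 9401), c(2500, 9500),
              c("g2", "g3"), TRUE),
    altEvents("r1", "retained_intron", "chrV", "+",
              1001, 1400, 701, 800, 801, 1000, 1401, 1600, 1601, 1700,
              "g4", TRUE)))
  cls <- suppressWarnings(c(mkTags("chrT", 1010, 1050),
                            mkTags("chrU", 2010, 2050),
                            mkTags("chrU", 9010, 9050),
                            mkTags("chrV", 1100, 1140)))
  rec <- associateClusters(cls, ev)
  counts <- countByCategory(rec)
  expect_equal(counts[["cassette_exon"]], 3L)
  expect_equal(counts[["retained_intron"]], 1L)
  expect_equal(sum(counts), sum(rec$associated))
  expect_setequal(names(counts),
                  c("cassette_exon", "retained_intron", "alt_5ss",
                    "alt_3ss", "alt_promoter", "alt_terminator"))
  expect_true(all(countByCategory(associateClusters(mkTags("chrZ", 1, 30),
                                                    ev)) == 0L))
})

test_that("permutation null is deterministic, flags undefined sd, and guards sizes", {
  ann <- smallAnn()
  cls <- mkTags(as.character(seqnames(ann$spans))[1:5],
                start(ann$spans)[1:5] + 100,
                start(ann$spans)[1:5] + 200,
                as.character(strand(ann$spans))[1:5])
  n1 <- permutationNull(cls, ann$events, ann$models, nTrials = 20, seed = 3)
  n2 <- permutationNull(cls, ann$events, ann$models, nTrials = 20, seed = 3)
  expect_identical(n1$expectedMean, n2$expectedMean)
  expect_identical(n1$expectedSd, n2$expectedSd)

  single <- permutationNull(cls, ann$events, ann$models, nTrials = 1, seed = 3)
  expect_true(all(is.na(single$expectedSd)))
  z <- zScores(countByCategory(associateClusters(cls, ann$events)), single)
  expect_true(all(is.na(z$z)))

  tooLong <- mkTags("x", 1, 10^7)
  expect_error(permutationNull(tooLong, ann$events, ann$models,
                               nTrials = 2, seed = 1), "longer")
})

test_that("z-scores follow the definition and never divide by zero", {
  null <- structure(list(
    expectedMean = setNames(c(10, 0, 0, 0, 0, 0),
                            c("cassette_exon", "retained_intron", "alt_5ss",
                              "alt_3ss", "alt_promoter", "alt_terminator")),
    expectedSd = setNames(c(5, 0, NA, NA, NA, NA),
                          c("cassette_exon", "retained_intron", "alt_5ss",
                            "alt_3ss", "alt_promoter", "alt_terminator")),
    nTrials = 100L), class = "PermutationNull")
  obs <- setNames(c(30L, 4L, 0L, 0L, 0L, 0L),
                  c("cassette_exon", "retained_intron", "alt_5ss",
                    "alt_3ss", "alt_promoter", "alt_terminator"))
  z <- zScores(obs, null)
  expect_equal(z$z[z$category == "cassette_exon"], 4.0)
  expect_true(is.na(z$z[z$category == "retained_intron"]))  # sd = 0
  obs["cassette_exon"] <- 10L
  expect_equal(zScores(obs, null)$z[1L], 0)
})

test_that("flanked-cassette selection applies all three filters", {
  ev <- suppressWarnings(c(
    toyCassetteEvent(),
    altEvents("noFlank", "cassette_exon", "chrU", "+",
              1001, 1100, 701, 800, 801, 1000, 1101, 1400, 1401, 1500,
              "g2", FALSE),
    altEvents("ri", "retained_intron", "chrV", "+",
              1001, 1400, 701, 800, 801, 1000, 1401, 1600, 1601, 1700,
              "g3", TRUE)))
  cls <- suppressWarnings(c(mkTags("chrT", 1010, 1050),
                            mkTags("chrU", 1010, 1050),
                            mkTags("chrV", 1100, 1140)))
  rec <- associateClusters(cls, ev)
  sel <- selectFlankedCassetteEvents(rec, ev)
  expect_equal(mcols(sel)$eventId, "ev1")
  ## not associated -> excluded
  rec2 <- associateClusters(mkTags("chrZ", 1, 30), ev)
  expect_length(selectFlankedCassetteEvents(rec2, ev), 0L)
})
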