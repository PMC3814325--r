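test_that("BED6 reading maps fields and coordinates, and validates input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t130\tt1\t0\t+",
               "chr2 200 260 t2 5 -"), f)
  tags <- readTagsBed(f)
  expect_length(tags, 2L)
  expect_equal(start(tags), c(101L, 201L))   # 0-based half-open in, 1-based in memory
  expect_equal(end(tags), c(130L, 260L))
  expect_equal(as.character(strand(tags)), c("+", "-"))
  expect_equal(mcols(tags)$tagId, c("t1", "t2"))
  expect_equal(unique(mcols(tags)$library), "clip")

  writeLines(character(), f)
  expect_length(readTagsBed(f), 0L)

  writeLines(c("chr1\t100\t130\tt1\t0\t+", "chr1\t500\t400\tt2\t0\t+"), f)
  expect_error(readTagsBed(f), "line\\(s\\) 2")

  writeLines("chr1\t100\t130\tt1\t0", f)     # no strand column
  expect_error(readTagsBed(f), "strand")
})

test_that("BED round trip preserves coordinates and strands bit-exactly", {
  set.seed(11)
  st <- sample(1:10000, 50)
  tags <- mkTags(sample(c("c1", "c2"), 50, TRUE), st,
                 st + sample(20:40, 50, TRUE),
                 sample(c("+", "-"), 50, TRUE))
  f <- withr::local_tempfile(fileext = ".bed")
  writeTagsBed(tags, f)
  back <- readTagsBed(f)
  expect_identical(start(back), start(tags))
  expect_identical(end(back), end(tags))
  expect_identical(as.character(strand(back)), as.character(strand(tags)))
  ## and writing again reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeTagsBed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GTF round trip preserves exon structure, CDS and roles", {
  ann <- smallAnn()
  f <- withr::local_tempfile(fileext = ".gtf")
  suppressWarnings(writeAnnotationGtf(ann$models, f))
  back <- readAnnotationGtf(f)
  expect_length(back, length(ann$models))
  ids <- vapply(back, geneId, character(1))
  for (g in seq_along(ann$models)) {
    a <- transcripts(ann$models[[g]])[[1L]]
    b <- transcripts(back[[match(geneId(ann$models[[g]]), ids)]])[[1L]]
    expect_identical(start(exons(a)), start(exons(b)))
    expect_identical(end(exons(a)), end(exons(b)))
    expect_identical(as.character(strand(exons(a))[1L]),
                     as.character(strand(exons(b))[1L]))
    expect_identical(cdsStart(a), cdsStart(b))
    expect_identical(cdsEnd(a), cdsEnd(b))
    expect_identical(exonRole(a), exonRole(b))
  }
})

test_that("CDS spanning two exons is re-expressed by cumulative exon lengths", {
  ## exons 501-600 and 701-800 (+); genomic CDS 551-600 + 701-740:
  ## transcript coords 51..140 by summing exonic lengths
  tx <- toyTranscript(c(100L, 100L), cdsStart = 51L, cdsEnd = 140L)
  cds <- cdsGenomicRanges(tx)
  expect_equal(start(cds), c(551L, 701L))
  expect_equal(end(cds), c(600L, 740L))
  f <- withr::local_tempfile(fileext = ".gtf")
  suppressWarnings(writeAnnotationGtf(list(GeneModel("toy_gene", tx)), f))
  back <- transcripts(readAnnotationGtf(f)[[1L]])[[1L]]
  expect_identical(cdsStart(back), 51L)
  expect_identical(cdsEnd(back), 140L)
})

test_that("transcript/genomic coordinate mapping is self-inverse on fuzzed intervals", {
  set.seed(42)
  for (rep in 1:20) {
    strand <- sample(c("+", "-"), 1)
    widths <- sample(50:150, sample(2:5, 1), replace = TRUE)
    L <- sum(widths)
    ce <- L - (L - 12L) %% 3L - 1L
    tx <- toyTranscript(widths, 10L, ce, strand = strand,
                        reference = FALSE)
    tpos <- sort(sample(seq_len(L), 2))
    gr <- transcriptToGenomic(tx, tpos[1], tpos[2])
    expect_equal(sum(width(gr)), tpos[2] - tpos[1] + 1L)
    ## endpoints map back
    gpos <- if (strand == "+") c(min(start(gr)), max(end(gr)))
            else c(max(end(gr)), min(start(gr)))
    expect_equal(genomicToTranscript(tx, gpos[1]), tpos[1])
    expect_equal(genomicToTranscript(tx, gpos[2]), tpos[2])
  }
})

test_that("alt event table round trips; unknown categories are skipped with a warning", {
  ev <- toyCassetteEvent()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAltEvents(ev, f)
  back <- readAltEvents(f)
  expect_equal(start(back), start(ev))
  expect_equal(mcols(back)$category, "cassette_exon")
  expect_identical(metadata(back)$skipped, 0L)

  ## inject an unknown category row
  lines <- readLines(f)
  extra <- sub("cassette_exon", "bleedingExon", lines[2])
  extra <- sub("ev1", "evX", extra)
  writeLines(c(lines, extra), f)
  expect_warning(back2 <- readAltEvents(f), "1 event row")
  expect_length(back2, 1L)
  expect_identical(metadata(back2)$skipped, 1L)
})

test_that("non-abutting event components raise an error naming the event", {
  expect_error(
    altEvents("evBad", "cassette_exon", "chrT", "+",
              1001, 1100, 701, 800, 801, 999,   # gap before the event
              1101, 1400, 1401, 1500, "g", TRUE),
    "evBad")
})

test_that("minus-strand events interpret upstream/downstream in transcript orientation", {
  ev <- toyCassetteEvent("-")
  ## upstream exon (transcript 5') is genomically rightmost
  expect_gt(mcols(ev)$upExonStart, end(ev))
  expect_lt(mcols(ev)$downExonEnd, start(ev))
  expect_silent(validateAltEvents(ev))
  ## the association region is the same genomic union either way
  expect_equal(start(associationRegions(ev)), 701L)
  expect_equal(end(associationRegions(ev)), 1500L)
})

test_that("region classification follows the precedence and partitions clusters", {
  ## coding gene: exons 501-600, 701-800 (+), CDS 51..140 (transcript)
  tx <- toyTranscript(c(100L, 100L), 51L, 140L)
  coding <- GeneModel("gA", tx)
  ## non-coding transcript on another contig
  nc <- TranscriptModel("ncA", "gB",
                        GRanges("chrN", IRanges(c(100, 400), width = 100),
                                strand = "+"))
  ncGene <- GeneModel("gB", nc)
  models <- list(coding, ncGene)
  clusters <- suppressWarnings(c(
    mkTags("chrT", 620, 660),      # fully inside the intron
    mkTags("chrT", 590, 640),      # straddles CDS exon and intron -> cds
    mkTags("chrT", 505, 520),      # 5' UTR (transcript coords 5..20)
    mkTags("chrT", 760, 790),      # 3' UTR side (coords > 140)
    mkTags("chrN", 120, 140),      # ncRNA exon
    mkTags("chrT", 5000, 5100),    # outside all spans
    mkTags("chrT", 620, 660, strand = "-")))  # wrong strand -> intergenic
  labels <- classifyClusterRegions(clusters, models)
  expect_equal(as.character(labels),
               c("intron", "cds", "5utr", "3utr", "ncrna",
                 "intergenic", "intergenic"))
  expect_equal(sum(table(labels)), length(clusters))
})
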