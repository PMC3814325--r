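## Shared fixtures and independent oracles. Everything here is built in
## code at test time; the heavier shared objects are created once per
## test run.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

emptyPeaks <- function() {
  data.frame(anchor = character(), offset = integer(),
             width = integer(), weight = numeric())
}

## a small, fast simulation setup used across unit tests
smallConfig <- function(...) {
  defaults <- list(n_genes = 20L, exons_per_gene = c(5L, 7L),
                   exon_length = c(120L, 180L),
                   intron_length = c(1000L, 1500L),
                   cassette_fraction = 0.5,
                   retained_intron_fraction = 0.1,
                   clip_library_size = 4000L,
                   control_library_size = 4000L)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

smallAnn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateAnnotation(smallConfig(),
                                                     seed = 1L,
                                                     genome = TRUE)
    cache
  }
})

## quick GRanges tag constructor (1-based closed)
mkTags <- function(chrom, start, end, strand = "+", lib = "clip") {
  n <- max(length(chrom), length(start))
  GRanges(chrom, IRanges(start, end), strand = strand,
          tagId = sprintf("t%03d", seq_len(n)), score = 0, library = lib)
}

## canonical toy cassette event: exon 701-800, intron 801-1000,
## cassette 1001-1100, intron 1101-1400, exon 1401-1500 (1-based closed)
toyCassetteEvent <- function(strand = "+") {
  if (strand == "+")
    altEvents("ev1", "cassette_exon", "chrT", "+",
              1001, 1100, 701, 800, 801, 1000, 1101, 1400, 1401, 1500,
              "geneT", TRUE)
  else
    altEvents("ev1", "cassette_exon", "chrT", "-",
              1001, 1100, 1401, 1500, 1101, 1400, 801, 1000, 701, 800,
              "geneT", TRUE)
}

## hand-buildable coding transcript from exon widths (plus strand);
## sequence supplied explicitly
toyTranscript <- function(widths, cdsStart, cdsEnd, intron = 100L,
                          strand = "+", chrom = "chrT",
                          reference = TRUE) {
  starts <- integer(length(widths)); starts[1L] <- 501L
  for (i in seq_len(length(widths) - 1L))
    starts[i + 1L] <- starts[i] + widths[i] + intron
  TranscriptModel("toy_tx", "toy_gene",
                  GRanges(chrom, IRanges(starts, starts + widths - 1L),
                          strand = strand),
                  cdsStart = cdsStart, cdsEnd = cdsEnd,
                  reference = reference)
}

## ---- independent oracles ----

## exact binomial upper tail by explicit PMF summation
binomTailOracle <- function(c, k, pi) {
  n <- c + k
  x <- c:n
  sum(choose(n, x) * pi^x * (1 - pi)^(n - x))
}

## Benjamini-Hochberg step-up re-derived from its definition:
## q_(i) = min_{j >= i} min(1, m * p_(j) / j) in sorted order
bruteStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- q
  out
}

## first stop codon via Biostrings translation (independent of the
## codon scan inside predictNmd); returns the 1-based transcript
## coordinate of the stop codon's first base, or NA
firstStopOracle <- function(seq, cdsStart) {
  s <- chartr("Uu", "Tt", as.character(seq))
  L <- nchar(s)
  ncod <- (L - cdsStart + 1L) %/% 3L
  if (ncod < 1L) return(NA_integer_)
  orf <- substr(s, cdsStart, cdsStart + 3L * ncod - 1L)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(orf),
                          if.fuzzy.codon = "X")))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0L) NA_integer_ else cdsStart + 3L * (as.integer(hit) - 1L)
}

## random coding toy transcript (+ its sequence) for NMD fuzzing
randomToyTranscript <- function() {
  ne <- sample(3:8, 1)
  widths <- sample(30:120, ne, replace = TRUE)
  L <- sum(widths)
  cs <- sample(1:10, 1)
  ncod <- sample(3:((L - cs - 2) %/% 3), 1)
  ce <- cs + 3L * ncod - 1L
  tx <- toyTranscript(widths, cs, ce, reference = TRUE)
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  list(tx = tx, seq = seq)
}
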