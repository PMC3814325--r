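# clipSpliceMap

CLIP-seq cluster calling, splicing maps and AS-NMD prediction for
regulatory-genomics analyses of RNA-binding proteins that control
alternative splicing.

The package addresses a recurring analysis pattern: a CLIP-seq
experiment maps where a protein binds pre-mRNAs, and the question is
whether that binding concentrates around *cassette exons* — exons that
can be included or skipped — and what skipping does to the transcript.
The prototype is a splicing repressor that binds the introns flanking a
cassette exon of its **own** pre-mRNA; skipping the exon shifts the
reading frame, introduces a premature termination codon (PTC) in the
next exon, and routes the transcript into nonsense-mediated decay
(NMD), closing an autoregulatory feedback loop.

## What it computes

* **Cluster calling against an IgG control.** After duplicate-tag
  removal, overlapping same-strand tags are chained into clusters. With
  `c` CLIP and `k` control tags and unique library sizes `N_c`, `N_k`,
  each cluster gets
  `fold = ((c+0.5)/N_c) / ((k+0.5)/N_k)` and the exact conditional
  binomial tail `p = P(X >= c)`, `X ~ Bin(c+k, N_c/(N_c+N_k))`, with
  Benjamini–Hochberg FDR control (`q <= 0.05` by default).
* **Region classification** of clusters (cds > 5'UTR > 3'UTR > ncRNA >
  intron > intergenic, strand-aware).
* **Association with alternative-splicing events** (an event counts as
  bound if a cluster overlaps the event or its immediate flanking
  introns/exons) and a per-category Z-score
  `z = (observed − mean)/sd` against a 100-trial permutation null that
  relocates clusters uniformly within expressed same-strand genes.
* **Normalized complexity maps**: for anchors at the cassette and
  flanking-exon splice sites, the fraction of events covered by at
  least one tag at each transcript-oriented offset (±500 nt), each
  event contributing at most 1 — with a control averaged over 100
  random sets of constitutive exons, and peak calling on the smoothed
  exceedance.
* **k-mer motif enrichment** (k = 5 or 6) of cluster RNA sequences over
  a composition-preserving shuffled (or genomic) background, with exact
  binomial window tests and BH q-values.
* **Splicing quantification and AS-NMD**: skipping ratio
  `skipped/(skipped+included)`, knockdown level relative to mock,
  `2^-ddCt`, exon-skip isoform construction, and NMD prediction by the
  50-nt last-exon-junction rule.
* **A seeded synthetic-data generator** (genome, annotation, cassette /
  retained-intron events, CLIP + control tag libraries with planted
  positional peaks and motifs, fold-enriched sites, noisy gel band
  intensities) that makes every stage testable against known truth.

## Worked example

```r
library(clipSpliceMap)

## a compact simulated study: 60 genes, 30 cassette exons, planted
## intronic binding around them
cfg <- simulationConfig(n_genes = 60L, exons_per_gene = c(5L, 7L),
                        intron_length = c(2000L, 3000L),
                        cassette_fraction = 0.5,
                        clip_library_size = 10000L,
                        control_library_size = 10000L)
ann  <- generateAnnotation(cfg, seed = 1)
clip <- simulateClipLibrary(ann, seed = 2)
ctrl <- simulateControlLibrary(ann, seed = 3)

## 1. CLIP clusters vs the IgG-like control
clusters <- callClusters(clip, ctrl)
sig <- clusters[S4Vectors::mcols(clusters)$significant]
```

```
clusters: 736 | significant (q <= 0.05): 120
  seqnames start  end strand clipCount controlCount      fold            q
1 gchr0001  5864 5995      -        32            2 13.143305 2.486902e-07
2 gchr0001  6175 6317      -        62            2 25.275587 3.315529e-15
3 gchr0001  6593 6700      -        31            3  9.099211 2.249433e-06
```

Significant clusters pile up 9–25-fold over the control. Are they near
cassette exons more often than chance?

```r
rec  <- associateClusters(sig, ann$events)
null <- permutationNull(sig, ann$events, ann$models, nTrials = 100, seed = 4)
zScores(countByCategory(rec), null)[1:2, ]
```

```
         category observed expected_mean expected_sd         z n_trials
1   cassette_exon       30         18.04   2.4075638  4.967677      100
2 retained_intron        0          1.32   0.5839607 -2.260426      100
```

All 30 cassette events are bound, five permutation standard deviations
above the ~18 expected from relocated clusters; retained-intron events
stay within the null band. The complexity map then shows *where* the
binding sits relative to the cassette 5' splice site:

```r
mapEvents <- selectFlankedCassetteEvents(rec, ann$events)
ctrlProf  <- controlProfile(clip, ann$models, setSize = length(mapEvents),
                            nSets = 100, seed = 5)
prof <- normalizedComplexity(clip, mapEvents, "cassette_5ss")
callMapPeaks(prof, ctrlProf)[, c("anchor", "offset", "value", "exceedance")]
```

```
        anchor offset value exceedance
1 cassette_5ss   -286     1   15.23455
2 cassette_5ss    115     1   17.38851
3 cassette_5ss    407     1   13.79873
```

The planted peaks at +100 and +400 nt downstream of the cassette 5'
splice site are recovered (at +115/+407 — coverage maps sit about half
a tag length 3' of the tag starts); the peak at −286 is the planted
3'-splice-site peak (150 nt upstream of the cassette exon) seen across
the ~140-nt exon from the 5'ss anchor. Finally, the AS-NMD call for the
skip isoform of the packaged cassette-exon fixture:

```r
fx <- fusLikeFixture()
sk <- skipExon(fx$transcript, 7L)
predictNmd(sk, transcriptSequence(sk, fx$genome))
```

```
NmdCall: predicted NMD substrate
  frameshift: TRUE
  PTC position: 574
  last junction: 1230
  PTC-to-junction: 656 nt
```

Skipping the 100-nt exon 7 shifts the frame; the first stop codon lands
at transcript position 574 — inside the exon-8 segment — 656 nt
upstream of the last exon–exon junction, far beyond the 50-nt rule, so
the isoform is predicted to be degraded rather than translated.

`runPipeline()` chains all stages (simulate → clusters → regions →
association → map → motifs → NMD) into one seeded, byte-reproducible
output directory with a hashed manifest.

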