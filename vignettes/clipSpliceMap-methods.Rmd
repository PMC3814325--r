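---
title: "Methods: CLIP cluster calling, splicing maps and AS-NMD prediction"
author: "clipSpliceMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CLIP cluster calling, splicing maps and AS-NMD prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

clipSpliceMap implements the computational core of a CLIP-seq splicing
study: calling protein-RNA binding clusters against a nonspecific-IgG
control library, associating clusters with alternative-splicing events
under a permutation null, building position-anchored normalized
complexity maps around cassette exons, scoring k-mer motif enrichment in
cluster sequences, and quantifying exon skipping together with a
nonsense-mediated-decay (AS-NMD) prediction for exon-skip isoforms. The
biological setting the package is modeled on is an RNA-binding protein
that binds introns flanking cassette exons — prototypically a splicing
repressor that binds a conserved cassette exon of its own pre-mRNA, so
that skipping that exon shifts the reading frame, introduces a premature
termination codon (PTC) in the next exon, and routes the transcript to
NMD, closing an autoregulatory feedback loop.

Everything is exercised against a synthetic-data generator with planted
signal, so each stage can be validated against known truth. Real data
enter through the same interfaces (BED6 tag libraries, GTF annotation,
FASTA genome, a tabular alternative-event file).

# Data model and coordinates

Intervals live in `GRanges` (1-based, closed), the native convention of
the GenomicRanges stack that performs all interval arithmetic; BED input
and output (0-based, half-open) and GTF (1-based) are converted at the
I/O boundary. Two S4 classes carry the annotation: `TranscriptModel`
(exons in genomic order, CDS bounds in 1-based transcript coordinates,
per-exon role flags constitutive/cassette/other) and `GeneModel`
(transcripts, an `expressed` flag standing in for an RNA-seq expression
filter, and the genomic span). Alternative-splicing events are a
`GRanges` whose range is the event interval with the flanking
introns/exons as metadata; a validity check enforces that the five
components tile a contiguous block, with "upstream" always meaning the
transcript 5' side (genomically reversed on minus-strand genes). All
overlap operations are strand-aware throughout: CLIP chemistry is
stranded, so a tag only counts toward features on its own strand.

# Cluster calling

Duplicate tags (identical chrom/start/end/strand) are removed first —
they are overwhelmingly PCR artifacts in CLIP libraries. Unique CLIP
tags on the same strand that share at least one base are chained into
candidate clusters; abutting half-open BED intervals share no base and
stay separate. A candidate needs a maximum simultaneous coverage
(`peakDepth`) of at least `minDepth` (default 2 — "overlapping tags"
means at least two). The control library is *not* clustered: it is a
background-rate estimator, and `controlCount` is the number of control
tags overlapping the final cluster extent.

Enrichment is scored with an exact conditional two-library test. With
`c` CLIP and `k` control tags in a cluster and unique library sizes
$N_c$, $N_k$:

$$\mathrm{fold} = \frac{(c + 0.5)/N_c}{(k + 0.5)/N_k}, \qquad
  p = P\!\left(X \ge c\right),\; X \sim
  \mathrm{Binomial}\!\left(c + k,\; \tfrac{N_c}{N_c + N_k}\right)$$

The 0.5 pseudocount keeps the fold finite at `k = 0`; the binomial
conditioning is the standard exact test for comparing two Poisson-like
tag counts and is fully specified (the original studies used a
peak-finder whose internals are not published; this package declares its
model instead). Benjamini-Hochberg adjustment (via `stats::p.adjust`)
across all candidates yields q-values; a cluster is significant at
`q <= alpha` (default 0.05). Test oracles re-derive the binomial tail by
explicit PMF summation and the BH step-up from its definition.

# Association with splicing events and permutation Z-scores

A cluster is associated with an event when it overlaps, on the same
strand, the contiguous region from the upstream flanking exon through
the downstream flanking exon (the event itself, its flanking introns, or
the flanking exons). An event supported by several clusters counts once.

The null model relocates every cluster — preserving its length and
strand — to a uniformly random position within the transcribed span of a
uniformly chosen expressed same-strand gene, then re-associates and
counts per category; with `n_trials = 100` the per-category mean and
sample (n−1) standard deviation give

$$z = \frac{\mathrm{observed} - \mathrm{expected\ mean}}
           {\mathrm{expected\ sd}}$$

with `z` reported as `NA` when the permutation sd is zero (never a
division by zero). This relocation null preserves the number and size
spectrum of clusters and their confinement to transcribed regions,
which we consider the minimal null consistent with an "expected count
from random trials" design; what exactly the original analyses
randomized is not documented, so the choice is declared, not inferred.

# Normalized complexity map

For each of four anchors — the upstream constitutive exon's 5' splice
site, the cassette 3' and 5' splice sites, and the downstream exon's 3'
splice site — the profile value at offset $d$ is the *fraction of
events* with at least one covering same-strand tag at transcript-
oriented offset $d$ (window ±500 nt; positive offsets run toward the
transcript 3' end, offset 0 is the terminal exonic base). Each event
contributes at most 1 at each offset regardless of its read depth; this
per-event saturation is the complexity normalization and makes the map
robust to a few deeply sequenced events. It also implies the invariant
used in testing: duplicating any one event's tags k-fold never changes
the profile.

We compute the profile over the full ±window at every anchor rather
than masking exon-body offsets beyond a short exon's length: a constant
denominator across offsets keeps `value(d) * n_events` an integer count
and makes the four anchor panels directly comparable; the price is that
exonic-side offsets beyond a short cassette exon read into the
neighboring intron, exactly as a genomic browser track would.

The control is an average over `n_sets = 100` random sets of `set_size`
internal constitutive exons from expressed genes (sampled without
replacement within a set, independently across sets), profiled at their
own 3'/5' splice sites. `set_size` defaults to the number of cassette
events so that case and control have the same sampling variance.

Peak calling smooths the profile and control mean with a centered
moving average (width 11 nt, odd; partial windows at the edges) and
thresholds the exceedance `(value − control mean)/control sd` at
`z = 3`, with the smoothed control sd floored at half a count
(`0.5/set_size`) to avoid degenerate divisions. Two numerical choices
matter and are worth stating plainly:

* **Localization on the value, not the z-score.** Strong binding
  saturates the per-event indicator, so profiles have flat tops; on a
  plateau the z surface fluctuates with the control sd rather than the
  signal. Peaks are therefore located as the midpoint of the
  near-maximal region of the smoothed *value* within each
  above-threshold run, which is stable on plateaus; the threshold
  decision stays on the exceedance.
* **Minimum supported width (`minRunWidth = 50` nt).** A genuine
  binding peak of the modeled kind (tag-placement spread ~30 nt, tags
  20–30 nt) produces an above-threshold footprint well over 100 nt; a
  chance pile-up of a handful of background tags produces only a narrow
  spike (tens of nt). Requiring the above-threshold run to span at
  least about two tag footprints rejects those spikes. This is why a
  background-only library yields *no called peaks* even though the
  pointwise maximum of ~4,000 correlated standardized offsets
  inevitably strays above 3 now and then — pointwise exceedance is not
  a usable flatness statistic; "no peaks called" is.

A reported peak position carries a small systematic shift of about half
a tag length (+10 to +15 nt for 20–30-nt tags) relative to the planted
tag 5'-end offset, because the map is built from full tag coverage: a
coverage-based profile is symmetric about `offset + (len − 1)/2`. This
is a property of coverage maps in general, not an artifact; recovery
tests allow ±20 nt accordingly.

# Motif enrichment

Cluster sequences are extracted strand-aware (reverse complement on the
minus strand) and transcribed to RNA. For k ∈ {5, 6}, all overlapping
windows are counted (a sequence of length L has L−k+1 windows). With
target rate `hits/windows` and background rate
`(bg hits + 0.5)/(bg windows + 1)`:

$$\mathrm{fold} = \frac{\mathrm{rate}_t}{\mathrm{rate}_b}, \qquad
  p = P\!\left(X \ge \mathrm{hits}\right),\;
  X \sim \mathrm{Binomial}(\mathrm{windows},\ \mathrm{rate}_b)$$

with BH q-values over all k-mers that have at least one target hit. The
default background is, per target sequence, ten independent uniform
permutations of its letters — length- and composition-preserving and
fully self-contained; a genomic mode (length-matched random draws from
a supplied genome, random strand) mirrors designs that sample the
reference genome instead. A position-weight-matrix discovery step is
deliberately out of scope: the claims this statistic supports are
k-mer-level (is a specific 6-mer, or GU/GGU-rich content, enriched?).
The `selectHighDepthSubregions` helper restricts the analysis to
clusters whose center depth strictly exceeds 100 tags, the "most
strongly bound sites" filter.

# Splicing quantification and AS-NMD

Gel quantification follows the band-ratio closed forms: skipping ratio
`skipped/(skipped + included)`; per-isoform knockdown level
`treated/mock`; qRT-PCR relative expression `2^-ddCt`. Band-intensity
linearity is assumed, as in densitometry practice.

`skipExon` removes an internal exon (the start codon must lie upstream),
shifts downstream transcript coordinates, and records the removed width.
`predictNmd` translates from the CDS start codon by codon until the
first UAA/UAG/UGA. A PTC exists when the first stop precedes the
annotated stop; the isoform is an NMD substrate when the PTC's first
base lies more than 50 nt upstream of the last exon–exon junction — the
canonical exon-junction-complex rule, adopted here as a declared,
configurable threshold (`junctionRule = 50`). Transcripts with no stop
before their end are flagged (`noStop`) and never called NMD. The test
oracle re-derives stop positions independently through
`Biostrings::translate`.

The packaged `fusLikeFixture()` is a deterministic 15-exon coding
transcript whose 7th exon is a 100-nt cassette exon (length not a
multiple of 3): skipping it shifts the frame so that the first stop
falls inside the 8th exon's segment, 656 nt upstream of the last
junction — the textbook AS-NMD geometry of a splicing repressor's
autoregulated exon.

# The synthetic-data generator as the study conditions

The generator is first-class, tested code; its defaults define the
conditions under which the pipeline is validated.

* **Annotation.** 870 single-transcript coding genes, one per contig,
  random strand, 11–13 exons of 120–180 nt separated by introns of
  8–12 kb. A cassette exon is planted in the middle of the exon chain
  in 10% of genes — yielding 87 cassette events, the size of the
  flanked-cassette set in the motivating study — always flanked by
  constitutive exons; 3% of the remaining genes carry a
  retained-intron event, represented over its exon–intron–exon block so
  that the event schema keeps abutting flanking introns and exons. The
  intron scale matters twice: it keeps 100k-tag libraries sparse enough
  that background tags do not chain into gene-length clusters, and
  dense planted sites do chain into single clusters.
* **CLIP library.** Each tag is background with probability 0.5
  (uniform over transcribed pre-mRNA spans; the original libraries'
  signal/background mix is unknown, so 0.5 is a stated default, not a
  claim), otherwise drawn from one of four planted peaks with weights
  0.2/0.1/0.1/0.1: +100 and +400 nt downstream of the cassette 5'
  splice site, 150 nt upstream of the cassette 3' splice site, and
  +300 nt downstream of the upstream constitutive exon — the canonical
  four-peak geometry of intronic binding around repressed cassette
  exons, with the 5'-splice-site-proximal peak strongest. Tag 5' ends
  (not centers) follow `round(Normal(anchor + offset, 30))`, mirroring
  5'-end-driven CLIP chemistry; tag length is drawn independently
  (20–30 nt); the tag body extends toward the transcript 3' end;
  offsets are transcript-oriented, so minus-strand genes double as the
  strand-handling test surface. The control library is background only.
* **Planted fold-enriched sites.** For cluster-calling validation, 50
  windows of 400 nt (one per sampled gene) receive extra CLIP mass so
  that the site-average CLIP density is exactly `fold` (default 10)
  times the control density at equal library sizes; the background
  share is solved from that constraint.
* **Band intensities.** Expected skipped/included intensities with
  independent multiplicative lognormal noise of a given coefficient of
  variation (mean-preserving parameterisation), so the noiseless case
  is exact.

Determinism: every generator is a pure function of (configuration,
seed); the RNG state of the caller is saved and restored around every
seeded operation.

What the generator deliberately does **not** emulate: sequencing
errors, PCR-duplicate families beyond exact-coordinate duplicates,
expression heterogeneity between genes, spliced (gapped) tag
alignments, crosslink-induced truncations, or multi-isoform genes.
Passing the validation suite therefore demonstrates the statistical
machinery under its stated model, not robustness to those real-data
complications.

# Validation scales and numerical choices

The test suite validates each stage at a scale where its statistics are
meaningful while a full run stays in the minutes range: cluster
recovery on 50 genes with 100k-tag libraries over five seeds (recall of
planted 10-fold sites ≥ 0.9 among q ≤ 0.05 clusters, empirical FDR
≤ 0.1); null calibration over 20 background-only replicates (fraction
of clusters at q ≤ 0.05 bounded by 0.05); complexity-map recovery of
all four planted peaks within ±20 nt over five seeds with a flat
background control; association Z-scores with z(cassette) ≥ 3 under
planted binding and |z| < 3 for all categories under uniform placement;
planted-CAGGUU recovery as the top-ranked 6-mer with fold ≥ 2 in at
least 9 of 10 seeds plus q-calibration under the null; and exact-oracle
agreement for the binomial tail (all c + k ≤ 25), the BH step-up (grid
p-vectors up to length 8), and the NMD codon scan (200 fuzzed
transcripts against independent translation).

Known limitations worth restating: the two-library binomial treats tags
as independent draws (no overdispersion model, no replicates); the
association null is one declared choice among several defensible
randomizations; complexity-map peak positions inherit the half-tag-
length coverage shift; the k-mer background preserves mononucleotide
but not dinucleotide composition; and the NMD rule is the 50-nt
heuristic, with no quantitative decay-efficiency model.
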