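---
title: "Methods: classifying ribosome-associated lncRNAs across datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying ribosome-associated lncRNAs across datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riboassoc` decides, per dataset and then across datasets, whether a long
non-coding RNA is bound by ribosomes and whether any of its putative ORFs
shows the signatures of active translation. This vignette documents the
model, the tunable parameters, the numerical conventions, and the design
choices that were genuinely open — the things a maintainer needs to know
before changing anything.

## The per-dataset model

The unit of evidence is a paired Ribo-seq / RNA-seq dataset aligned to the
transcriptome (not the genome: mapping short footprints across splice
junctions is noisy, so only annotated transcripts are quantified). Reads are
used only on the sense strand, as produced by strand-specific footprint
protocols. A read mapping to `N` transcripts is allocated by expression
weight, `w(i) = RPKM(i) / sum_n RPKM(n)`, with RNA-seq RPKM precomputed once
from uniform-weight counts — a deliberately simple, documented quantifier
(no EM, no iteration; the weights-from-expression step is run exactly once,
and all-zero-expression multimappers fall back to uniform weights because
the ratio is 0/0 there). A read with more placements than `max_hits`
(default 100) is discarded entirely, and any read with at least one
placement on a contaminant transcript (rRNA, tRNA, snoRNA, miRNA) is
removed from *all* transcripts, since footprint-sized fragments of abundant
structural RNAs multimap promiscuously.

Ribosome density of a region of length $L$ with weighted footprint count
$r$ on a transcript of expression $E$ (RPKM) is $d = r / (E \cdot L)$.
Counting a read into a region by its 5' end is a choice: it matches the
frame-analysis convention and guarantees each read is counted in exactly
one region. The association cutoff is empirical: the 90th percentile of
$d$ over 3'UTRs of expressed mRNAs (RPKM $\ge 1$, inclusive). The 3'UTR
sits downstream of the stop codon and is approximately ribosome-free, so
its density distribution is a null for "no association"; taking the 90th
rather than a higher percentile tolerates genuine 3'UTR ribosome signal
(e.g. rescue events) while still letting the vast majority of translating
mRNAs exceed the cutoff. Classification is inclusive at the cutoff. mRNAs
are scored on their CDS density, lncRNAs on whole-transcript density;
3'UTRs shorter than `min_utr3_len` (default 30 nt) are excluded from the
cutoff sample because a handful of nucleotides cannot estimate a density.
Transcripts below the expression threshold are excluded from both the
cutoff sample and classification — density is undefined at $E = 0$ and
unstable just above it.

## Coding-potential metrics

Putative ORFs are ATG-to-stop runs of length $\ge$ 30 nt including the stop
codon, one per (frame, stop): the ORF anchored at the most 5' in-frame ATG
not preceded by another in-frame stop. Nested ORFs sharing a stop add no
separable footprint signal, so only the longest is scored; codons
containing N never act as start or stop (conservative). All ORFs of a
transcript are scored and the transcript takes the best result.

Three metrics, all oriented so that higher = more CDS-like, all cut at the
10th percentile of the same metric computed on expressed,
ribosome-associated mRNA CDSs (so 90% of calibration mRNAs pass by
construction), all inclusive at the cutoff:

* **FLOSS (transformed).** Footprint-length histograms are restricted to
  the 25–35 nt window (the sizes a ribosome protects), renormalized, and
  compared by total variation; the score is $1 - \mathrm{TV}$. It is
  computed per *transcript* — length composition is a property of the whole
  footprint population, not of one ORF — and attached to each ORF of the
  transcript.
* **RRS (scaled).** With one pseudo-read on each of the four counts, the
  raw score is the in-ORF over downstream footprint density ratio divided
  by the same ratio in RNA-seq. For mRNA CDSs the downstream region is the
  annotated 3'UTR; for lncRNA ORFs, the stop-to-transcript-end stretch (the
  closest analogue of a 3'UTR; an ORF whose stop coincides with the
  transcript end is unassessable for RRS). The unbounded ratio is mapped to
  $[0, 1)$ by $x/(1+x)$ — monotone, fixed point $0.5$ at ratio 1.
* **Frame score.** The 5'-end frame distribution of an ORF (add-one
  smoothed per frame) is compared to the pooled CDS frame distribution by
  Kullback–Leibler divergence in natural log; the base only rescales a
  percentile-thresholded quantity, so it cannot change any pass/fail call.
  For the shared "pass if $\ge$ cutoff" rule the divergence is transformed
  to $\exp(-KL) \in (0, 1]$, a strictly decreasing bijection, so
  thresholding the similarity is exactly equivalent to thresholding the
  divergence. Using the pooled CDS distribution as reference (rather than
  assuming ideal frame-0 dominance) absorbs dataset-specific digestion and
  trimming offsets.

The number of filters passed, maximized over a transcript's ORFs, is its
translation level A0–A3 in that dataset; a transcript without a putative
ORF is A0.

## Cross-dataset integration

Over $M$ selected datasets with expression indicator $x(i)$ and association
sign $y(i) \in \{+1, -1\}$:

$$\mathrm{spec} = \frac{M - x}{M - 1}, \qquad
  \mathrm{RAI} = \frac{\sum_i x(i)\, y(i)}{\sum_i x(i)}, \qquad
  \mathrm{TS} = \sum_{i \in \text{associated}} w(\alpha(i))$$

with level weights $w = (-1, -0.5, 0.5, 1)$ for A0–A3. $M$ counts the
*selected* datasets and must be at least 2 (the $M-1$ denominator is the
guard; a single-dataset run is a hard error). Binary $y$ is used because
densities are normalized within each dataset and are not comparable across
datasets. `RAI * (1 - spec)` rewards association replicated across broadly
expressed datasets and is the catalog's ranking score; `RAI * spec` is its
complement for tissue-specific transcripts, and the two sum to RAI (an
asserted identity). Classes use strict inequalities at the 5th/95th
percentiles of `RAI * (1 - spec)` and at the top-5% TS threshold within the
ribo class: ties fall to the non-extreme class, so a value sitting exactly
on a threshold is never promoted. Transcripts expressed in no dataset have
undefined RAI and are reported unscored. The 5th/95th thresholds are
computed over all lncRNAs with defined RAI; a minimum-expressed-datasets
filter is exposed (`min_datasets`) for stricter catalogs.

Dataset selection applies three criteria with strict thresholds: both
mapping rates > 0.30, lncRNA-vs-CDS footprint length distance < 0.15, and
per tissue only the dataset with the smallest distance (ties broken
lexicographically by dataset id). Mapping rates are taken as given from
aligner logs; estimating them from raw reads is out of scope.

All empirical percentiles in the package — the 3'UTR cutoff, the coding
cutoffs, the catalog thresholds, the TS threshold — use linear
interpolation between order statistics (`quantile()` type 7), fixed in one
helper because every cutoff value depends on the convention.

## Enrichment statistics

Class-wise support enrichment uses the one-sided Fisher exact test; the
p-value is the upper hypergeometric tail. Two effect sizes are reported
side by side: the conditional maximum-likelihood odds ratio (the Fisher
estimator) and the risk ratio $(a/(a{+}b)) / (c/(c{+}d))$ — the support-rate
ratio between the class and the rest. Published lncRNA-catalog support
tables report rate ratios under the "odds ratio" label, and reproducing
those printed values requires the risk ratio, so both are first-class
outputs. Group comparisons (expression, localization or NMD fold changes
between classes) use Welch's t-test by default, with the pooled-variance
variant available.

## What the simulator emulates — and what it does not

`simulate_study()` generates the statistical structure the method relies
on, with ground truth: mRNAs partitioned into 5'UTR (60–200 nt), CDS
(240–780 nt) and human-like 3'UTRs (150–1200 nt); lncRNAs (~400–900 nt)
each carrying an embedded ATG-to-stop ORF; a few abundant rRNA-like
contaminants whose reads also multimap onto lncRNAs. Translating regions
receive ~29 ± 1.2 nt footprints with 85% of 5' ends snapped to frame 0 of
the active ORF and downstream coverage suppressed to 5% of the in-ORF
rate; untranslated and background footprints are broader (31 ± 3 nt,
clipped 22–38) and aperiodic. Ribosome-associated-but-untranslated lncRNAs
carry uniform occupancy at 0.6x the translating footprint rate (log-normal
spread 0.6): ribosome-bound, clearly above the noise floor, but a minority
of borderline transcripts whose calls flip across datasets — as in real
multi-tissue panels. Free lncRNAs and mRNA 3'UTRs draw their background
rate from one common law, which is precisely what gives the 90th-percentile
cutoff its intended operating point (about 10% of truly free transcripts
will always sit above it; perfect specificity is impossible by
construction, and tests should expect ~0.90, not 1.0). Expression dropout
is per dataset — 10% for mRNAs, 35% for lncRNAs, reflecting the tissue
specificity of lncRNA expression — and dropout means true absence: at
desk-scale library sizes an RPKM threshold cannot represent
"present but sub-threshold" abundance, so unexpressed simply means zero
reads. Default study size is 10 datasets (a realistic multi-tissue panel
that also gives the spec statistic a fine lattice) with 60 transcripts per
class, and read depth of 6 reads/kb per RPKM unit per covered region;
validation runs use three such studies, a size chosen to keep the full
pipeline comfortably re-runnable on a laptop.

Not emulated: sequencing errors and quality trimming (reads are emitted as
already-aligned SAM; the package's scope starts at alignments), UMIs,
realistic rRNA sequence content, isoform-level ambiguity beyond a simple
two-placement multimap model, P-site offsets, and initiation-site
profiling. Passing tests on simulated data therefore demonstrate that the
statistical machinery recovers planted structure under the model's own
assumptions — not that those assumptions hold in any particular real
library; on real data the dataset-selection QC stage exists precisely to
reject libraries whose footprint length distributions do not behave.

## Degenerate inputs and edge policies

Zero-footprint transcripts are unassessable for FLOSS (the low-level
function errors; the pipeline treats them as failing that filter); ORFs
with empty downstream regions are unassessable for RRS; frame
distributions are always defined thanks to the pseudocounts (a read-free
ORF scores the uninformative uniform triple). An empty 3'UTR cutoff
sample, fewer than 10 calibration CDSs, fewer than 20 scored lncRNAs, a
single dataset, and an all-zero library are all hard errors rather than
silent defaults. The `1e-9`-style pseudo value used when log-scaling
density plots is plotting-only and never enters classification.

## Known limitations

Per-transcript FLOSS blurs multi-ORF transcripts; RRS for lncRNA ORFs
depends on the chosen downstream region (stop to transcript end) and is
undefined for stop-at-end ORFs; the binary association sign discards
density magnitude, which the composite scores only partly recover; and the
catalog thresholds are relative (percentile-based), so class sizes scale
with the catalog rather than with an absolute effect size. The composite
score lattice is coarse when few datasets are available — ties at the
extremes then shrink the noribo/ribo classes, which is the intended
conservative behaviour of the strict inequalities.
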