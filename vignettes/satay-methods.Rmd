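---
title: "Methods: from junction reads to essential genes, domains and interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from junction reads to essential genes, domains and interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, and the numerical choices made where the
method leaves room for decisions. The companion README shows the surface
API; here we document *why* each step is what it is.

## The screen and its signal

A saturated transposon screen mutagenizes a yeast population with a
MiniDs transposon until nearly every non-essential position of the genome
is hit in some clone — on the order of 300,000 distinct insertion sites,
one per ~40 bp. Sequencing reads start at the transposon–genome junction,
so after alignment the 5′-most aligned base of each read (leftmost
reference base for `+` alignments, rightmost for `−`) estimates the
insertion coordinate. Genes whose disruption prevents growth leave
insertion-free intervals; genes whose disruption is advantageous in a
condition accumulate reads. Everything downstream is statistics on the
resulting insertion map.

Coordinates are 0-based half-open throughout the package; GFF3 I/O
converts from the 1-based inclusive convention and BED is native. This
makes interval lengths and boundary arithmetic (`start <= pos < end`)
exact and unambiguous.

## Collapsing reads into insertions

Sequencing is imperfectly accurate near the junction, so two reads of the
same orientation mapping within 2 bp are taken to originate from the same
transposon. The pairwise rule is closed transitively along sorted
positions (single-linkage): reads at 100, 102, 104 on one strand collapse
into one insertion even though the extremes differ by 4 bp. Single
linkage is the only order-independent closure of a pairwise rule, and it
is what a one-pass scan over sorted positions computes. The
representative coordinate is the modal read position (ties broken toward
the smaller coordinate): sequencing errors shift a minority of reads, so
the mode is the best junction estimate. Read counts are kept raw — the
downstream positive-selection statistics use raw read totals — and no PCR
de-duplication is attempted beyond the merging itself.

Multimapping reads (MAPQ 0) are discarded by default, mirroring the
discard of reads on repetitive DNA (rDNA, Ty elements, subtelomeric
repeats) whose placement is ambiguous. `min_mapq` and the tolerance are
exposed as parameters (defaults 1 and 2 bp).

## Per-gene counts

Genes are the genomic spans of their CDS annotation, multi-part CDS
collapsed to min-start..max-end: yeast introns are rare and short, and
insertion maps are drawn over gene bodies. Whether sub-CDS resolution
(spliced parts) would change per-gene counts is an open question we
resolved in favour of spans; users wanting other feature classes can pass
any interval table. Insertions are counted into every gene whose span
contains them — overlapping genes are counted independently, with no
arbitration, which is why dubious ORFs overlapping essential genes appear
transposon-free. Strand is ignored: both orientations disrupt. Counting
uses an interval-overlap sweep (`GenomicRanges::findOverlaps`), never a
quadratic scan; a test checks the sweep against a brute-force double loop
on random instances.

Candidate essential genes are reported threshold-free by default (the
per-gene table); `call_depleted_genes()` flags genes at or below an
explicit transposon-count threshold, because classification in practice
is by inspection against known annotation rather than a canonical cutoff.

## The essential-domain likelihood score

For each gene, with in-gene insertion positions sorted, the score is

> (longest interval from transposon *n* to transposon *n + 5*) ×
> (transposons in the gene) / (gene length)^1.5,

zeroed when fewer than 20 transposons map to the gene, when the longest
interval is shorter than 300 bp, or when it covers more than 90% or less
than 10% of the gene. The three conditions are applied in that order and
the first failure is recorded, so a zero score is always explained.

Two decisions deserve notice:

- **Boundary padding.** Virtual transposons are placed at −1 and at the
  gene length before the gap scan (default on, exposed as a flag).
  Without padding, an insertion-free region at a gene's 5′ or 3′ end —
  the dominant real case — can never be spanned by any *n* → *n + 5*
  interval, and such genes would be unscorable.
- **Duplicate coordinates.** Two insertions at the same base on opposite
  strands count as two transposons for *N* (it mirrors "total transposons
  mapping to the gene") but as one position for the gap geometry.

`k` = 5 and the 20/300 bp/10–90% thresholds are configuration with these
defaults. The score's exponent 1.5 balances domain length against gene
length: a free block of fixed relative size scores higher in shorter
genes, where it is less likely by chance.

## Volcano comparison of library sets

Per gene and library, the transposon count is normalized to the library's
total mapped transposons. The fold change is the mean normalized count in
the experimental set over that in the reference set; the p-value is a
two-sided two-sample Student's t-test on the normalized values — the
classic pooled-variance test (a Welch variant sits behind a flag). Counts
(not densities) are the default metric; density is available because the
field uses both phrasings.

Numerical policies:

- **Pseudocount** of half a transposon per gene per library before
  normalization. Fold changes must be finite for insertion-free genes —
  precisely the interesting ones. Exposed as a parameter.
- **Zero-variance groups** (all replicate values identical on both
  sides): the t statistic is undefined and the p-value is reported absent
  rather than 0 — fabricated certainty is worse than a missing value.
- **No multiple-testing correction by default** (volcanoes plot raw
  p-values); Benjamini–Hochberg is available as an option.

A note on discriminative power: with 3 + 3 libraries the pooled t has 4
degrees of freedom, and its fat tails set a hard limit on how cleanly a
handful of truly depleted genes can outrank ~1000 null genes on p-value
alone. A power sketch (Poisson per-gene counts, pooled t) shows that for
20 planted lethal genes to occupy exactly the 20 smallest p-values in
≥95% of experiments, mean per-gene counts near 400 are required — several
times deeper than a typical saturated library (~40 per gene at one
insertion per 42 bp). At realistic saturation the planted genes dominate
the extreme ranks but a few short genes are regularly overtaken by null
fluctuations. This is a property of the test statistic, not of the
implementation; replicate number, not library depth, is the effective
remedy.

## Genome-scale signals

**Density track.** A per-base insertion indicator convolved with a
centered boxcar (default 40 bp), edges truncated to the available bases so
values stay in transposons/bp. The track integrates to the insertion
count per chromosome up to edge effects.

**Periodicity.** The correlogram of the density track is computed at
integer-bp lags (`stats::acf`) and the period is read off as a peak in a
search band (default 50–500 bp). Two numerical choices make this robust
where the naive "highest local maximum" is not: peak prominence is
*topographic* (height above the higher of the two key saddles), with an
adaptive floor of `max(0.01, 9/sqrt(track length))` matched to the
sampling noise of a correlogram — white-noise tracks therefore report no
period; and because a periodic signal repeats its correlogram peak at
every multiple of the period with near-equal height, the estimator
descends from the strongest peak to the fundamental (the smallest
comparable-height peak near an integer fraction of its lag). Correlogram
read-off was chosen over an FFT periodogram because it matches how the
plot is read and behaves well on short tracks.

**Cross-correlation** against a nucleosome-occupancy track reports the
Pearson correlation per offset and its extrema. For an anti-phased
sinusoidal signal the minima at offset 0 and ±period are equivalent
phases; consumers should interpret the argmin modulo the period.

**Pericentromeric enrichment.** For each chromosome, the cumulative count
C(d) of insertions within distance d of the centromere grows linearly in
d under a uniform background (both arms accumulate at a constant rate);
a localized pericentromeric excess adds a constant offset once d exceeds
the bump scale. The intercept of an OLS fit of C(d) on d over the linear
part therefore estimates the per-chromosome excess, and the summed
intercepts over the library total give the enriched fraction. The fit
range is configuration (default 50–300 kb from each centromere, 1 kb
grid): the lower bound must clear the bump (decay ~10 kb), the upper must
stay within the shortest arm considered; the estimate is always reported
with the range used. Chromosomes without a centromere or shorter than the
range are excluded with a warning and do not change the fraction's
denominator.

**Sequence context.** Base frequencies in a window around a seeded random
sample of insertion sites, reverse-complemented for minus-strand
insertions so the profile is oriented by the transposon. An unbiased
integrase reproduces the genome background (38% GC in yeast) at every
offset.

## What the simulator emulates — and what it does not

The generator produces genomes, annotations and libraries with the
statistical structure the analyses assume, plus truth tables:

- insertion intensity `1 + a·sin(2πx/P)` with defaults P = 160 bp,
  a = 0.5 — the nucleosome effect is modelled as a phase, not as explicit
  nucleosome positions, because only the periodicity is analyzed;
- a pericentromeric component contributing an expected fraction
  (default 20%) of insertions as exponential bumps (decay 10 kb) at every
  centromere; the component split is drawn once per library
  (Binomial(n, f)) and each component filled to its quota, so the
  fraction is well-posed regardless of component-specific rejection
  rates;
- zero intensity inside essential genes and essential domains, so planted
  truth is exact;
- read counts 1 + Geometric(p) with p set so the median is 22 — the
  heavy right tail is qualitatively PCR-like; only the median is
  calibrated;
- strands Bernoulli(1/2); exactly n distinct (chrom, position, strand)
  sites per library, and no two same-orientation sites within the 2 bp
  merging tolerance — a property real *collapsed* maps have by
  construction, and which makes the SAM emission round-trip through the
  mapper exactly;
- condition libraries by per-gene fitness: insertions thinned with
  probability 1 − min(fitness, 1), reads multiplied by max(fitness, 1).

Defaults are a 16-chromosome genome of 750 kb chromosomes (12 Mb, the
yeast scale) with centromeres at mid-arm, 1000 genes of 0.3–3 kb, 20%
essential, GC 0.38. Everything is deterministic given the seed.

Not emulated: sequencing error and read trimming (the package consumes
aligned reads), restriction-fragment amplifiability dropout (a uniform
thinning knob suffices), chromatin beyond the sinusoidal phase, biological
correlation between gene length and essentiality. Passing tests on
simulated data therefore demonstrate the estimators' correctness under
the stated generative model, not robustness to alignment artefacts or to
chromatin structure the model lacks.

## Problem sizes used by the test-suite

The suite exercises the estimators at desk scale, chosen so each
statistical check retains its power: periodicity recovery on a 200 kb
chromosome with 5000 insertions (the autocorrelation band is then within
±5% of the planted 160 bp); centromere recovery on the full 16×750 kb
genome with 10^5 insertions (the intercept estimator is then within ±3
percentage points of the planted 20%); essential-gene recovery and the
volcano benchmark at one insertion per 42 bp over a 2 Mb genome with 1000
genes — the saturation of a deep real library, at which insertion-free
calling is near-perfect while, as discussed above, exact top-20 p-value
occupancy with 3 + 3 replicates is beyond the pooled t's power.

## Known limitations

- The merging rule collapses genuinely distinct transposons inserted
  within 2 bp in the same orientation; dense regions (pericentromeres)
  therefore undercount slightly. This is inherent to the rule, not to the
  implementation.
- The domain score is gap-based and does not consult protein-domain
  databases; intervals are reported in gene coordinates and mapping onto
  protein structure is out of scope.
- The centromere estimator assumes arms longer than the fit range; on
  genomes with short arms the range must be narrowed, widening the
  intercept's variance.
- p-values from 3 + 3 libraries carry 4 degrees of freedom; ranking by
  p-value is reliable for strong effects but the tail probabilities
  themselves are fragile. More replicates help more than deeper
  libraries.
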