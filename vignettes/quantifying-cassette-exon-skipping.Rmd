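---
title: "Quantifying cassette-exon skipping from splice-junction reads"
author: "skipquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cassette-exon skipping from splice-junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipquant)
```

## The measurement

A cassette exon is an internal exon that transcripts either include or
skip between two constitutive flanking exons. Skipping leaves a direct
splice between the flanking exons, so RNA-seq reads whose alignments span
exon–exon junctions carry the evidence: for target exon *t*, reads over
the two inclusion junctions (*t−1 → t* and *t → t+1*) support inclusion,
and reads over the skipping junction (*t−1 → t+1*) support exclusion.
With counts `j12`, `j13`, `j23` (named after the exon 1–2, 1–3 and 2–3
junctions of the motivating CD19 exon 2 event), the percent spliced in is

$$\mathrm{PSI} = \frac{j_{12} + j_{23}}{j_{12} + j_{13} + j_{23}}.$$

This three-count form weighs both inclusion junctions against the single
skipping junction. It is the canonical statistic here; the MISO-style
alternative that first averages the two inclusion counts,
$\tfrac{(j_{12}+j_{23})/2}{(j_{12}+j_{23})/2 + j_{13}}$, is available as
`psiVariant = "standard"` for sensitivity analysis and is never larger
than the three-count form (they agree exactly when `j13 = 0`).

The clinical context: CD19Δexon2 transcripts produce a CD19 protein whose
FMC63 epitope region (exons 3–4) loses structural support, impairing
recognition by FMC63-derived CAR constructs. Exon 2 PSI is therefore an
RNA-level proxy for the abundance of an antigen-escape variant, and the
interesting signal is a *low* PSI.

## Parameters and defaults

* **Minimum junction depth, 30 reads** (`minJunctionDepth`). PSI is a
  ratio of small counts; below a few dozen reads the estimate is unstable,
  so samples with `j12 + j13 + j23 < 30` get an undefined PSI and the
  classification `insufficient_depth`. The depth is the sum over the three
  event junctions only, keeping the statistic self-contained rather than
  depending on what other junctions exist in the locus. Whether any
  skipping read was seen (`j13 ≥ 1`, "measurable skipping") is recorded
  regardless, because a single skipping read is meaningful evidence even
  when a stable ratio is not computable.
* **Inclusion threshold, 90 %** (`inclusionThreshold`), compared
  inclusively: PSI ≥ 0.90 classifies as `near_complete_inclusion`. This is
  a conservative screening threshold, not a clinically validated cutoff.
* **Extraction filters** (`ExtractionConfig`): minimum overhang of 6
  aligned bases on each side of a splice (suppresses 1–3 bp split
  artifacts while keeping short-anchor sensitivity), minimum MAPQ 10 with
  255 treated as "unavailable" and kept, duplicates and
  secondary/supplementary alignments excluded so each fragment's primary
  evidence counts once. Counting is read-level: both mates of a pair
  spanning the same junction count as two reads, matching the semantics of
  common junction tables. Junction matching is exact-boundary and
  unstranded by default (library strandedness is often unknown);
  near-miss junctions are surfaced by `junctionDiagnostics()` but never
  counted.
* **Uncertainty**: `psiInterval()` gives the Wilson score interval for the
  inclusion proportion, which behaves sensibly at the 0/1 boundaries and
  collapses onto the point estimate as depth grows. It treats the three
  counts as inclusion-vs-skipping Bernoulli draws; it is a readability
  aid, not a model of biological variation.

## Coordinate conventions

Exons are stored as 1-based inclusive genomic intervals and junctions as
the 1-based inclusive interval of the excised intron — the native
GenomicRanges convention. All tabular I/O converts at the boundary:
`junctionBounds()`, BED export and the CLI print the 0-based half-open
`[intron_start, intron_end)` convention of BED-like junction tables, and
STAR `SJ.out.tab` ingestion converts from its 1-based first/last intron
base columns. The conversion is a single ±1 on the start, applied in
exactly one place per format.

Exon numbering is transcript-relative and strand-aware: exon 1 is the
5′-most exon of the mRNA, so on the minus strand it has the largest
genomic coordinates. When a gene has several transcripts and none is
requested, `loadGeneModel()` prefers a canonical-tagged transcript, then
the transcript with most exons, then the longest genomic span, then the
lexicographically smallest ID — a deterministic choice that matters
because "exon 2" is only meaningful relative to one transcript's exon set.
Only exact-boundary junctions are counted; alternative donor/acceptor
usage near the target exon is reported diagnostically, not quantified.

## The simulator

Because the cohorts that motivate this pipeline live in controlled-access
or large public repositories, every stage is validated against a
generative model with known ground truth.

**Generative model.** A sample has a latent skipping fraction *s*: the
fraction of transcripts lacking the target exon. Each inclusion transcript
offers two junction classes, each skipping transcript one, so with equal
junction detection efficiency the junction-read class probabilities are
$\big(\tfrac{1-s}{2-s}, \tfrac{s}{2-s}, \tfrac{1-s}{2-s}\big)$ and the
expected PSI is

$$\mathrm{PSI}(s) = \frac{2(1-s)}{2-s},$$

a strictly decreasing bijection of [0, 1] onto itself that happens to be
its own inverse. `simulateJunctionTriple()` draws the triple from the
corresponding multinomial; `simulateSplicedReads()` goes further and emits
a toy reference FASTA plus a coordinate-sorted SAM whose junction reads
have `aM gN bM` CIGARs placed uniformly over valid anchor offsets, with
optional plain exonic reads for the coverage track and optional spurious
junctions with random incorrect boundaries. Output is byte-identical given
a seed. An optional per-junction efficiency vector lets tests probe the
equal-efficiency assumption, which is the same assumption implicit in
summing raw counts in the PSI formula.

**Cohort presets.** Four presets emulate the study groups at their sample
sizes: `ball_like` (75 treatment-naïve B-cell acute lymphoblastic
leukemia), `dlbcl_like` (553 diffuse large B-cell lymphoma), `blood_like`
(1048 whole blood) and `spleen_like` (255 spleen). Per-sample *s* follows
a zero-inflated Beta: with probability `w0` a sample carries no skipping
transcript at all (biologically, the variant is absent rather than merely
rare), otherwise `s ~ Beta(a, b)`. The zero-inflation is what lets a
cohort combine a high near-complete-inclusion proportion with a broad
measurable-skipping fraction; a plain Beta cannot produce the left-skewed
shape the tight cohorts show. The (a, b, w0) values were fixed by a
one-off least-squares calibration so the *expected-PSI* distribution of
each preset matches its cohort's reported median, quartiles and (where
achievable with two shape parameters) its ≥90 %-inclusion proportion;
`configuredMedianPsi()` exposes the median each preset encodes, and that
is the oracle simulated cohorts are tested against. Junction depths are
negative binomial: near-Poisson (size 3–4, mean 250–400) for the
homogeneous cohorts and strongly overdispersed (size 1.2, mean 150) for
the lymphoma preset, so a realistic minority of lymphoma samples fails
the 30-read filter.

The `cart_case` series plants the four-patient CAR-T cohort: skipping
counts 21, 13, 1 and 0 for the rapid-relapse patient, non-responder,
slow-relapse patient and complete responder, each below the depth filter,
so the intended surface is the descriptive `junctionReport()` (raw counts
and skipping rank, deliberately no PSI column). The inclusion-junction
counts in this preset are synthetic placeholders — only the skipping
counts and response labels follow the emulated series.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: positional coverage bias (3′/5′ decay, GC),
mappability differences between junctions, alignment and base-calling
error, intron-retention reads, tumor-purity dilution by normal B cells,
and any dependence between depth and skipping fraction. The
equal-efficiency default is an explicit modeling choice, not a claim about
real junction detectability.

## Numerical choices

* Quartiles use linear interpolation between order statistics
  (`quantile(..., type = 7)`, R's default); published summaries rarely
  state their quantile convention, so this one is documented to make IQR
  comparisons reproducible.
* Cohort proportions are computed over depth-passing samples by default;
  published denominators are sometimes ambiguous, so
  `denominator = "all"` is available.
* Histogram bins are left-closed with 1-percentage-point width; a PSI of
  exactly 100 falls in the [100, 101) bin, and the binned counts are
  emitted as a table so the figure content is testable.
* Transcript-selection ties break deterministically (see above);
  `junctionReport()` ranks ties by the minimum rank.
* Degenerate inputs: depth 0 never defines a PSI even with the filter at
  0; an all-inclusion cohort yields IQR (1, 1) and zero measurable
  skipping; an empty post-filter cohort raises an error rather than
  returning NaNs.
* Extraction skips alignments whose CIGAR begins or ends with a splice
  (no anchor at all) with a warning, and applies the overhang rule per
  splice within multi-junction reads.

## Verification strategy and problem sizes

The test suite checks extraction against an independent base-by-base
expansion oracle on randomized alignments (100 files of up to 200 reads,
up to 3 splices per read, with indels, clipping and filterable flags);
statistical recovery of $\mathrm{PSI}(s)$ at depth $10^5$ over 100 seeds
per skipping fraction (within three multinomial standard errors of the
closed form); exact identity of the full
simulate → extract → match → compute chain on planted triples at depth
2000; and cohort medians of the presets against their configured values
at the emulated sample sizes. The Wilson interval is checked against the
uncorrected score interval of `prop.test()`. These sizes give
comfortable statistical resolution for every property tested while
keeping the suite quick to run.

## Limitations

Single-event scope: no multi-exon events, no intron retention, no
isoform-level deconvolution — PSI here is a within-gene ratio at one
cassette exon. Bulk counts cannot distinguish uniform low-level skipping
across cells from a subclone expressing only the variant. PSI inherits
compositional confounding: samples rich in normal B cells expressing the
canonical isoform will show elevated inclusion regardless of the
malignant clone's splicing. And the depth filter means low-expression
samples are reported descriptively, not quantified — by design.
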