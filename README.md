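# skipquant

Quantify cassette-exon skipping from splice-junction reads.

## The problem

Approved anti-CD19 CAR-T constructs recognize an FMC63 epitope encoded by
CD19 exons 3–4, and the CD19Δexon2 splice variant — transcripts skipping
exon 2 — destabilizes that epitope and has been linked to antigen escape
and relapse. The RNA-level readout for the variant is the **percent spliced
in (PSI)** of the cassette exon, computed from the reads that span the
three splice junctions of the skipping event. For CD19 exon 2 these are
the exon 1–2, exon 1–3 and exon 2–3 junctions:

```
PSI = (j12 + j23) / (j12 + j13 + j23)
```

where `j12` and `j23` are reads supporting the two inclusion junctions and
`j13` reads supporting the skipping junction. A lower PSI means more exon
skipping. PSI is computed only for samples with at least 30 junction reads
across the event (the denominator is unstable at near-zero depth); samples
with PSI ≥ 90 % are classified as near-complete inclusion.

skipquant implements this pipeline for any cassette exon, for
bulk or single-sample RNA-seq, with audiences in mind who work either from
aligned BAM/SAM files or from precomputed junction tables (STAR
`SJ.out.tab`, BED-like recount3/snapcount exports):

* `loadGeneModel()` / `deriveCassetteEvent()` — derive the three event
  junctions from a GTF gene model (transcript-relative exon numbering);
* `extractJunctions()` — CIGAR-walk split-read counting with overhang,
  MAPQ and flag filters; `readStarJunctions()` / `readJunctionBed()` for
  precomputed tables; `matchEvent()` for exact-coordinate lookup;
* `computePsi()` / `computePsiTable()` — depth-filtered PSI with Wilson
  score intervals and classification;
* `summarizeCohort()`, `junctionReport()`, `plotPsiHistogram()`,
  `plotSashimi()` — cohort summaries and figures;
* `simulateSplicedReads()`, `simulateCohort()`, `cohortPreset()`,
  `simulateCartCohort()` — ground-truth simulators that make every stage
  verifiable without external data.

## Worked example

```r
library(skipquant)

## a toy 4-exon cassette gene; real use: loadGeneModel("anno.gtf", "CD19")
model <- toyGeneModel()
event <- deriveCassetteEvent(model, targetExon = 2)
event
#> CassetteEvent: exon 2 of TOY1 (TOY1.t1)
#>   inclusion_upstream    ctg1:[500,800) +
#>   skipping              ctg1:[500,1400) +
#>   inclusion_downstream  ctg1:[1100,1400) +

## PSI for one sample: 50 + 40 inclusion reads, 10 skipping reads
computePsi(junctionTriple(50, 10, 40))
#> PsiResult 'sample': depth 100, PSI 90.0%, near_complete_inclusion, measurable skipping: TRUE
```

The junction coordinates print in the 0-based half-open BED convention.
The PSI of 90.0 % sits exactly on the inclusive classification threshold,
and the single skipping read count is flagged as measurable skipping.

A simulated heterogeneous lymphoma-like cohort (553 samples, zero-inflated
Beta skipping fractions, overdispersed junction depths):

```r
sim <- simulateCohort(cohortPreset("dlbcl_like", seed = 3))
summarizeCohort(computePsiTable(sim$triples))
#> CohortSummary 'dlbcl_like': 450/553 samples pass the depth filter
#>   median PSI 92.1% (IQR 86.5-96.2), min 61.5%
#>   near-complete inclusion: 58.4%  measurable skipping: 89.3% (of passing samples)
```

About one in five samples fails the 30-read depth filter at this cohort's
depth distribution; among passing samples roughly 58 % reach near-complete
inclusion while 89 % carry at least one skipping read — the broad,
left-tailed PSI distribution that distinguishes the lymphoma-like preset
from the tight high-inclusion leukemia/blood/spleen presets.

A command-line wrapper over the same functions is installed at
`inst/scripts/skipquant` (subcommands `event`, `extract`, `ingest`, `psi`,
`summarize`, `simulate`).

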