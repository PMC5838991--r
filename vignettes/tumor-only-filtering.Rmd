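---
title: "Tumor-only somatic filtering and interpretation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic filtering and interpretation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosieve)
```

## The problem

Tumor-only panel sequencing — common for archival FFPE material where a
matched normal cannot be collected — cannot distinguish somatic mutations
from germline polymorphisms or platform artifacts by subtraction. The
standard defense is a cascade of independent rules, each targeting one
contaminant class. `oncosieve` implements that cascade together with the
downstream interpretation layers (copy number, mutational burden, cohort
profiling, actionability) as plain, auditable predicates.

## The filtering model and its assumptions

A call survives the cascade iff all five predicates hold. Because each
predicate depends only on the variant's own fields (plus two static
resources, the blacklist and the repeat mask), the kept set is invariant
under filter order; the printed order is kept only so decision traces read
naturally and so a removed variant can be attributed to a *first failing
filter* in the run manifest.

| filter | rule | boundary semantics |
|---|---|---|
| functional class | class ∈ {missense, stopgain, frameshift indel, non-frameshift indel} | exact set membership |
| population frequency | removed iff 1000g > 0.01 **or** ExAC > 0.01 | strict `>`; missing = 0 |
| panel of normals | removed iff key detected in > 20% of normals | detection: reads ≥ 3 (inclusive), VAF > 0.01 (strict); recurrence strict |
| repeat mask | removed iff position inside a masked interval | BED half-open; 1-based position converted once |
| evidence tier | COSMIC: VAF > 0.01 and reads ≥ 5; else VAF > 0.02 and reads ≥ 8 | VAF strict, reads inclusive |

Strict-versus-inclusive choices follow the rules' own phrasing ("above
1%", "a minimum of 5"); every boundary is unit-tested on an exhaustive
grid (VAF ∈ {0.0099, 0.01, 0.0101, 0.02, 0.0201} × reads ∈ {4, 5, 7, 8} ×
COSMIC ∈ {T, F}).

Assumptions worth stating: population frequency annotations, COSMIC
membership and functional classes are consumed as inputs and trusted; a
missing population frequency is treated as "never observed", which
deliberately errs toward keeping novel variants; and the blacklist rule is
a pure counting rule — no statistical model of sequencing error, no depth
normalization across normals (the normals are assumed comparably deep).

### Variant identity

Blacklist matching requires one key per variant across samples. The key is
`(chrom, pos, ref, alt)` after stripping an optional `chr` prefix and
trimming the shared ref/alt prefix (advancing `pos`) then any shared
suffix. This unifies the common redundant indel spellings without needing
the reference sequence; matching is allele-specific by design — a
different alternate allele at a blacklisted site is kept.

## Copy number

Given per-bin mean coverages for tumor and reference, the per-bin statistic
is `log2((t / median(t)) / (r / median(r)))`; medians are genome-wide
per-sample medians, removing library-size differences without modeling GC
content. Bins of a gene are averaged into one segment — a deliberate
replacement of HMM segmentation, because the interpretation layer only
consumes gene-level gain/loss statements. The classification cutoff is
±0.6 in log2 (≈ 1.5-fold gain, 0.66-fold loss), **inclusive** at the
boundary: the cutoff value itself is the reported fold change, so it
counts as a call. Bins with zero or missing coverage on either side are
dropped with a warning; a non-finite segment ratio is an error, never a
silent neutral.

## Tumor mutational burden

`TMB = eligible mutations / panel Mb`, where eligible classes equal the
cascade keep-list (stopgain counts as non-synonymous; synonymous and
splice calls do not count) and the denominator is the merged unique panel
footprint. Copy-number events are excluded from the numerator. Absolute
TMB values are only comparable between panels of known footprint; the
synthetic panel is ~0.3 Mb, so synthetic TMB values are high relative to
values quoted for multi-megabase panels.

## Cohort profiling and actionability

The co-mutation matrix maps classes to display categories (stopgain and
frameshift → `truncating`; CNV gain → `amplification`). Gene and pathway
frequencies count *patients*, not alterations; a pathway counts a patient
once regardless of how many member genes are hit. Mutual exclusivity is
reported descriptively (patients altered in ≥ 2 genes of a set) with no
significance test, and no multiple-testing correction is applied anywhere
— the workflow is descriptive, not inferential, except for the explicit
Fisher-exact cohort-vs-reference comparison, which takes the reference
cohort's size explicitly rather than assuming one.

ClinVar annotations are lists of assertions; a record is flagged
pathogenic only when some assertion is Pathogenic/Likely_pathogenic *and*
none is Benign/Likely_benign. Records with conflicting submissions are
therefore not asserted pathogenic — the package's own rule, chosen so that
a conflicting record (e.g. `Likely_benign;pathogenic`) does not outrank a
clean pathogenic assertion.

The actionability knowledge base is a flat TSV so evidence can be edited
without code changes. Pattern types: exact protein change (compared after
stripping `p.`, removing whitespace, upper-casing — printed notations are
inconsistent about spaces), truncation class (nonsense/frameshift),
amplification, splice disruption (intronic offset notation in the cDNA
string), and any-deleterious (SIFT). Class-level rules (e.g. any TP53
nonsense) are intentional: actionability evidence for tumor suppressors is
usually class-level, not allele-level.

Two open choices resolved here: splice-site calls are dropped by the
default keep-list but a `keep_splice` switch exists, because actionable
splice disruptions (e.g. in NF1) do occur and users consuming
externally-filtered tables may need them; and the primary caller's depth
threshold (≥ 20) is available as an optional pre-filter but off by
default, since it belongs to the upstream caller, not the cascade.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure the cascade
assumes, with defaults fixed to the study conditions of the motivating
cohort: 15 tumors, 53 normals, tumor depth ≈ 300×, normal depth ≈ 700×,
somatic VAFs Beta(2, 8) (mean 0.2, giving a realistic share of
below-threshold subclonal calls), ~8 somatic and ~10 germline variants per
tumor, population frequencies from a two-point mixture (0.05 common /
0.0001 rare — the filter only tests a threshold, so a full site-frequency
spectrum would add nothing), 30 artifact sites of which half are injected
into 30% of normals (recurrent, above the 20% rule) and half into 10%
(sporadic, below it), a 10% repeat-masked fraction, and per-patient CNV
shifts of log2 ±1 with multiplicative log-normal noise of sd 0.1. The
panel is 60 genes × 10 bins × 500 bp (0.3 Mb) — a scaled-down stand-in
for a 416-gene panel that keeps the full pipeline runs in the test suite
fast while leaving every rule exercised; the CNV recovery property is
additionally checked at 50 bins/gene. Clinical covariates loosely match
the motivating cohort's margins (12/15 male; stage I/II/III = 4/7/4)
purely for realistic fixtures.

Evidence fields are generated so that `alt_reads = round(vaf × depth)`
exactly, and random streams are split per component (clinical, artifacts,
variants, coverage) so changing one knob does not perturb the others;
identical seed and configuration reproduce the bundle byte-for-byte.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: FFPE damage signatures (C>T deamination), GC- or
mappability-driven coverage waves, strand bias, tumor purity and
subclonal structure, shared germline haplotypes across individuals, and
base-level sequencing error. The recovery results (100% of common germline
and recurrent artifacts removed, 100% of above-threshold somatic kept) are
properties of deterministic rules applied to cleanly labelled input; on
real data, rare germline variants and sporadic artifacts pass the cascade
by construction — the known, accepted leakage of tumor-only calling,
visible in the generator's leakage report.

## Numerical and degenerate-input choices

* Empty variant tables flow through every stage (empty kept set, empty
  trace, zero TMB); an empty normal cohort or empty panel footprint is an
  error, not a zero.
* Validation errors name the offending row and field; file readers prefix
  the path.
* Duplicate detections of one key within one normal count once —
  recurrence is across samples.
* TSV round-trips are exact: missing numerics are empty cells, and the
  generator rounds where needed so written values re-read identically.

## Known limitations

Tumor-only specificity is bounded: rare germline variants are
indistinguishable from somatic ones under these rules. No purity/ploidy
correction enters the CNV calls, so the ±0.6 cutoff under-calls events in
low-purity samples. The blacklist assumes the normals were produced on the
same platform and pipeline as the tumors. TMB from small panels has high
variance and is not comparable across panel designs.
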